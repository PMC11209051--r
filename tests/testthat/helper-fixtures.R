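# In-code fixtures: small frames with known pixel content.

# A frame whose parenchyma is a centred square; optional mediastinum band.
uniform_frame <- function(value = 100, size = 30, mm_per_pixel = 0.5,
                          band_rows = NULL, band_value = NULL,
                          capsule_value = NULL) {
  px <- matrix(as.integer(value), size, size)
  parenchyma <- matrix(TRUE, size, size)
  mediastinum <- matrix(FALSE, size, size)
  capsule <- matrix(FALSE, size, size)
  if (!is.null(band_rows)) {
    mediastinum[band_rows, ] <- TRUE
    parenchyma <- parenchyma & !mediastinum
    if (!is.null(band_value)) px[band_rows, ] <- as.integer(band_value)
  }
  if (!is.null(capsule_value)) {
    capsule[1, ] <- TRUE
    parenchyma[1, ] <- FALSE
    px[1, ] <- as.integer(capsule_value)
  }
  ultrasound_frame(px, mm_per_pixel,
                   masks = list(parenchyma = parenchyma,
                                mediastinum = mediastinum,
                                capsule = capsule))
}

# Paint a filled rectangle of flow pixels into a logical matrix.
paint_rect <- function(m, r1, r2, c1, c2) {
  m[r1:r2, c1:c2] <- TRUE
  m
}

default_parenchyma_mask <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fr <- render_bmode_frame(maturation_profile(), week = 30, seed = 1)
      cache <<- fr$masks$parenchyma
    }
    cache
  }
})
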