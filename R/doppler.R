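# Colour-Doppler vascularity scoring (modified Gumbsch scale, 0-4).
#
# Flow components are 8-connected sets of coloured overlay pixels. A
# component is "distinct" when its size reaches the distinct-pixel threshold;
# the vessel "course" is deemed visible when a component is sufficiently
# elongated (major/minor axis ratio) or long (principal-axis chord length, a
# skeleton-length proxy for thin structures).

label_components_8 <- function(mask) {
  coords <- which(mask)
  if (length(coords) == 0) return(list())
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- integer(nr * nc)
  nb <- c(-1, 1, -nr, nr, -nr - 1, -nr + 1, nr - 1, nr + 1)
  row_of <- function(idx) ((idx - 1) %% nr) + 1
  comps <- list()
  k <- 0
  for (s in coords) {
    if (lab[s] != 0) next
    k <- k + 1
    stack <- s
    lab[s] <- k
    members <- integer(0)
    while (length(stack) > 0) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      members <- c(members, cur)
      r <- row_of(cur)
      for (d in nb) {
        nx <- cur + d
        if (nx < 1 || nx > nr * nc) next
        # guard against wrapping across matrix columns
        dr <- abs(row_of(nx) - r)
        if (dr > 1) next
        if (mask[nx] && lab[nx] == 0) {
          lab[nx] <- k
          stack <- c(stack, nx)
        }
      }
    }
    comps[[k]] <- members
  }
  lapply(comps, function(m) {
    cbind(row = ((m - 1) %% nr) + 1, col = ((m - 1) %/% nr) + 1)
  })
}

component_features <- function(coords) {
  n <- nrow(coords)
  ctr <- colMeans(coords)
  cv <- if (n > 1) stats::cov(coords) else matrix(0, 2, 2)
  cv <- cv + diag(1 / 12, 2)     # pixel quantization variance
  e <- eigen(cv, symmetric = TRUE)
  elong <- sqrt(max(e$values) / max(min(e$values), 1e-12))
  proj <- (coords[, 1] - ctr[1]) * e$vectors[1, 1] +
    (coords[, 2] - ctr[2]) * e$vectors[2, 1]
  structure(list(
    pixel_count = n,
    bbox = c(row_min = min(coords[, 1]), row_max = max(coords[, 1]),
             col_min = min(coords[, 2]), col_max = max(coords[, 2])),
    elongation = max(elong, 1),
    skeleton_length = diff(range(proj)) + 1
  ), class = "vessel_component")
}

#' Detect colour-flow components in a Doppler overlay
#'
#' Finds 8-connected components of flow pixels that intersect the parenchyma,
#' discarding components below `min_pixels` as noise. Components are returned
#' sorted by size, largest first.
#'
#' @param overlay logical matrix of flow pixels (or 0/1 matrix).
#' @param parenchyma_mask logical matrix, same shape.
#' @param min_pixels minimum component size kept.
#' @return list of `vessel_component` objects (`pixel_count`, `bbox`,
#'   `elongation`, `skeleton_length`).
#' @export
detect_vessels <- function(overlay, parenchyma_mask, min_pixels = 5) {
  if (!identical(dim(overlay), dim(parenchyma_mask))) {
    stop("overlay and parenchyma mask shapes differ")
  }
  ov <- overlay != 0
  comps <- label_components_8(ov)
  keep <- Filter(function(co) {
    nrow(co) >= min_pixels && any(parenchyma_mask[co])
  }, comps)
  feats <- lapply(keep, component_features)
  feats[order(-vapply(feats, `[[`, numeric(1), "pixel_count"))]
}

#' Assign a modified Gumbsch vascularity score
#'
#' Score 0: no flow detected. Score 1: only sub-threshold colour signals.
#' Score 2: one to three distinct signals (components at or above the
#' distinct-size threshold). Score 3: more than three distinct signals.
#' Score 4: the course of a vessel is visible (an elongated or long
#' component); course visibility dominates component counting.
#'
#' @param components list from [detect_vessels()].
#' @param distinct_pixels minimum size of a "distinct" signal.
#' @param course_elongation major/minor axis ratio marking a vessel course.
#' @param course_length principal-axis chord length (pixels) marking a
#'   vessel course.
#' @return list of class `doppler_score`: `score`, `n_components`,
#'   `n_distinct`, `course_visible`.
#' @export
score_doppler <- function(components, distinct_pixels = 10,
                          course_elongation = 4, course_length = 30) {
  if (distinct_pixels <= 0 || course_elongation <= 0 || course_length <= 0) {
    stop("thresholds must be positive")
  }
  n <- length(components)
  if (n == 0) {
    return(structure(list(score = 0L, n_components = 0L, n_distinct = 0L,
                          course_visible = FALSE), class = "doppler_score"))
  }
  sizes <- vapply(components, `[[`, numeric(1), "pixel_count")
  course <- any(vapply(components, function(x) {
    x$elongation >= course_elongation || x$skeleton_length >= course_length
  }, logical(1)))
  n_distinct <- sum(sizes >= distinct_pixels)
  score <- if (course) 4L else if (n_distinct > 3) 3L else
    if (n_distinct >= 1) 2L else 1L
  structure(list(score = score, n_components = as.integer(n),
                 n_distinct = as.integer(n_distinct),
                 course_visible = course), class = "doppler_score")
}

#' @export
print.doppler_score <- function(x, ...) {
  cat(sprintf("<doppler_score> %d (%d components, %d distinct%s)\n",
              x$score, x$n_components, x$n_distinct,
              if (x$course_visible) ", course visible" else ""))
  invisible(x)
}

#' Tabulate Doppler scores for a set of testes
#'
#' @param scores integer vector of per-testis scores (0-4).
#' @return named numeric vector `score0` ... `score4` of percentages, rounded
#'   half-up to integers (sum 100 plus or minus 1).
#' @export
#' @examples
#' score_cohort(c(rep(4, 13), rep(3, 3)))
score_cohort <- function(scores) {
  scores <- scores[!is.na(scores)]
  if (length(scores) < 1) stop("at least one scored frame is required")
  if (!all(scores %in% 0:4)) stop("scores must lie in 0..4")
  counts <- vapply(0:4, function(s) sum(scores == s), numeric(1))
  pct <- floor(100 * counts / length(scores) + 0.5)
  names(pct) <- paste0("score", 0:4)
  pct
}

#' Reference proportions of Doppler scores by week
#'
#' The week-specific score distribution used by the synthetic generator:
#' no detectable flow through week 20, first signals at week 22, and only
#' scores 3-4 after week 32, with more than 80 percent of testes showing a
#' visible vessel course from week 36.
#'
#' @return data.frame: `week` and percentage columns `score0` ... `score4`.
#' @export
doppler_score_table <- function() {
  tab <- rbind(
    c(22, 69, 31, 0, 0, 0),
    c(24, 31, 19, 44, 6, 0),
    c(26, 69, 19, 12, 0, 0),
    c(28, 6, 13, 31, 37, 13),
    c(30, 0, 6, 25, 44, 25),
    c(32, 0, 0, 0, 25, 75),
    c(34, 0, 0, 0, 19, 81),
    c(36, 0, 0, 0, 19, 81),
    c(38, 0, 0, 0, 19, 81),
    c(40, 0, 0, 0, 12, 88)
  )
  early <- cbind(seq(4, 20, 2), 100, 0, 0, 0, 0)
  out <- as.data.frame(rbind(early, tab))
  names(out) <- c("week", paste0("score", 0:4))
  out
}

# Largest-remainder apportionment of n testes to the five score classes.
apportion_scores <- function(percents, n) {
  q <- percents * n / 100
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- q - base
    extra <- order(-frac, seq_along(frac))[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}
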