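# Two-colour colocalisation with a chance-coincidence model.

#' Chance colocalisation probability
#'
#' The probability that a focus in one channel falls within the matching
#' area of a randomly placed focus of the other channel:
#' `C = (A_R / A_FOV) * n`, where `A_R` is the focus (matching) area,
#' `A_FOV` the field-of-view area and `n` the number of foci. By default
#' `A_R` is the matching disc `pi * radius^2`.
#'
#' @param A_R Focus area, px^2.
#' @param A_FOV Field-of-view area, px^2.
#' @param n Number of foci.
#' @return An object of class `coloc_chance`: list with `A_R`, `A_FOV`,
#'   `n`, `C`.
#' @export
chance_colocalization <- function(A_R, A_FOV, n) {
  assert_scalar_num(A_R, "A_R", 0, strict_lower = TRUE)
  assert_scalar_num(A_FOV, "A_FOV", 0, strict_lower = TRUE)
  if (A_R > A_FOV) stopf("`A_R` must not exceed `A_FOV`")
  assert_scalar_num(n, "n", 0)
  C <- A_R / A_FOV * n
  if (C > 1) warnf("chance colocalisation C = %.3g exceeds 1", C)
  structure(list(A_R = A_R, A_FOV = A_FOV, n = n, C = C),
            class = "coloc_chance")
}

#' @export
print.coloc_chance <- function(x, ...) {
  cat(sprintf("<coloc_chance> C = %.4g (A_R %.3g px^2, A_FOV %.3g px^2, n = %g)\n",
              x$C, x$A_R, x$A_FOV, x$n))
  invisible(x)
}

#' Two-colour focus colocalisation
#'
#' Foci from two channels (same frame and registration) are matched
#' one-to-one, greedily by ascending centroid distance (ties broken by
#' lowest index), accepting only pairs within `radius`. The colocalised
#' fraction is reported relative to channel A — the reference channel
#' (the DNA channel when scoring loaded helicases on DNA). The pair set is
#' symmetric in channel order; only the denominator of the fraction
#' changes.
#'
#' @param foci_a,foci_b Data frames with columns `x`, `y` (reference
#'   channel first).
#' @param radius Matching radius, px (default 2).
#' @param fov_area Field-of-view area in px^2 for the chance model;
#'   `NULL` to skip.
#' @return An object of class `coloc_result`: list with `pairs` (data
#'   frame `a`, `b`, `distance`), `fraction_colocalised`, `n_a`, `n_b`,
#'   `radius` and `chance` (a [chance_colocalization()] using `n_b` foci,
#'   or `NULL`).
#' @export
colocalize <- function(foci_a, foci_b, radius = 2, fov_area = NULL) {
  if (radius <= 0) stopf("`radius` must be positive")
  na <- nrow(foci_a); nb <- nrow(foci_b)
  pairs <- data.frame(a = integer(0), b = integer(0), distance = numeric(0))
  if (na > 0 && nb > 0) {
    d <- sqrt(outer(foci_a$y, foci_b$y, `-`)^2 +
              outer(foci_a$x, foci_b$x, `-`)^2)
    cand <- which(d <= radius, arr.ind = TRUE)
    if (nrow(cand)) {
      ord <- order(d[cand], cand[, 1], cand[, 2])
      cand <- cand[ord, , drop = FALSE]
      used_a <- rep(FALSE, na); used_b <- rep(FALSE, nb)
      for (i in seq_len(nrow(cand))) {
        ai <- cand[i, 1]; bi <- cand[i, 2]
        if (used_a[ai] || used_b[bi]) next
        used_a[ai] <- TRUE; used_b[bi] <- TRUE
        pairs <- rbind(pairs,
                       data.frame(a = ai, b = bi, distance = d[ai, bi]))
      }
    }
  }
  chance <- if (!is.null(fov_area))
    chance_colocalization(pi * radius^2, fov_area, nb) else NULL
  structure(list(pairs = pairs,
                 fraction_colocalised = if (na > 0) nrow(pairs) / na
                                        else NA_real_,
                 n_a = na, n_b = nb, radius = radius, chance = chance),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> %d pairs / %d reference foci (fraction %.3f, radius %g px)\n",
              nrow(x$pairs), x$n_a, x$fraction_colocalised, x$radius))
  if (!is.null(x$chance))
    cat(sprintf("  chance coincidence C = %.4g\n", x$chance$C))
  invisible(x)
}

#' Write a colocalisation report as JSON
#'
#' @param res A [colocalize()] result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_coloc_json <- function(res, path) {
  out <- list(pairs = res$pairs,
              fraction_colocalised = res$fraction_colocalised,
              n_a = res$n_a, n_b = res$n_b, radius = res$radius,
              chance = if (!is.null(res$chance)) unclass(res$chance))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
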