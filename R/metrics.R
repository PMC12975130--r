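#' Excess kurtosis of a nuclear intensity sample
#'
#' Fisher excess kurtosis with population (biased) moments:
#' `g2 = m4 / m2^2 - 3`, `m_k = mean((x - mean(x))^k)`. Zero for a Gaussian;
#' affine-invariant, so between-condition comparisons do not depend on the
#' intensity scale.
#'
#' @param x Numeric vector of pixel intensities within one nuclear mask
#'   (n >= 4, non-constant).
#' @return Excess kurtosis (scalar); `NA` with a warning for zero variance.
#' @export
nuclear_kurtosis <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 4L) input_error("kurtosis needs n >= 4 finite values")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) {
    warning("zero variance: kurtosis undefined")
    return(NA_real_)
  }
  mean((x - m)^4) / m2^2 - 3
}

#' smFISH copies per cell
#'
#' Total detected molecule maxima divided by total nuclei, pooled across
#' fields (total/total, not the mean of per-field ratios).
#'
#' @param n_maxima Integer vector of per-field molecule maxima.
#' @param n_nuclei Integer vector of per-field nucleus counts.
#' @return Copies per cell (scalar).
#' @export
copies_per_cell <- function(n_maxima, n_nuclei) {
  if (length(n_maxima) != length(n_nuclei))
    input_error("per-field maxima and nuclei must align")
  if (any(n_maxima < 0) || any(n_nuclei < 0))
    input_error("counts must be non-negative")
  tot_n <- sum(n_nuclei)
  if (tot_n == 0) input_error("zero nuclei")
  sum(n_maxima) / tot_n
}

#' Non-reference allele frequency at a site
#'
#' @param counts Named numeric vector of base counts (names among
#'   A/C/G/T).
#' @param ref Reference base.
#' @param min_depth Minimum total depth (default 50); below it the site is
#'   flagged and no value returned.
#' @return List with `frequency` (`NA` when flagged), `depth`, `flagged`.
#' @export
allele_frequency <- function(counts, ref, min_depth = 50) {
  if (any(counts < 0)) input_error("base counts must be non-negative")
  if (!ref %in% names(counts)) input_error("reference base not in counts")
  depth <- sum(counts)
  if (depth < min_depth)
    return(list(frequency = NA_real_, depth = depth, flagged = TRUE))
  list(frequency = (depth - counts[[ref]]) / depth, depth = depth,
       flagged = FALSE)
}

#' Wound-healing migration rate
#'
#' `R_M = (W_i - W_t) / t` in um/h; negative values (wound widening) are
#' allowed.
#'
#' @param w_initial Initial average wound width (um).
#' @param w_t Average wound width at time `t` (um).
#' @param t Elapsed time (h, > 0).
#' @return Migration rate in um/h.
#' @export
migration_rate <- function(w_initial, w_t, t) {
  assert_scalar_number(t, "t", lower = 0, strict_lower = TRUE)
  (w_initial - w_t) / t
}

#' Wound closure fraction
#'
#' `closure = (A0 - At) / A0`; also returns the normalized wound area
#' `At / A0` (the two sum to 1) and the closure percentage.
#'
#' @param a0 Wound area at time 0 (um^2, > 0).
#' @param at Wound area at the later time point (um^2).
#' @return List with `closure`, `percent`, `normalized_area`.
#' @export
wound_closure <- function(a0, at) {
  assert_scalar_number(a0, "a0", lower = 0, strict_lower = TRUE)
  assert_scalar_number(at, "at", lower = 0)
  cl <- (a0 - at) / a0
  list(closure = cl, percent = 100 * cl, normalized_area = at / a0)
}
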