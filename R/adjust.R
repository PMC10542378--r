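## Family-wise (Holm) and FDR (Benjamini-Hochberg) p-value adjustment.
## Adjusted p-values are returned rather than accept/reject flags so that
## thresholds stay with the caller.

.checkP <- function(p) {
  p <- as.numeric(p)
  if (!length(p)) stop("empty p-value family")
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must be finite and within [0, 1]")
  p
}

#' Holm (step-down Bonferroni) adjustment
#'
#' Step-down family-wise error control: with the family sorted ascending,
#' the i-th adjusted value is `min(1, max_{j <= i} (m - j + 1) p_(j))`,
#' returned in the original order. Used for the seven-region prediction
#' family.
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same order and names as `p`.
#' @examples
#' holmAdjust(c(0.036, 0.112, 0.078, 0.205, 0.468, 0.163, 0.752))
#' @export
holmAdjust <- function(p) {
  x <- .checkP(p)
  out <- p.adjust(x, method = "holm")
  names(out) <- names(p)
  out
}

#' Benjamini-Hochberg (step-up FDR) adjustment
#'
#' `adjusted_(i) = min_{j >= i} min(1, m p_(j) / j)` on the sorted family,
#' original order restored. Used across the candidate set of the model-path
#' search.
#'
#' @inheritParams holmAdjust
#' @return Adjusted p-values, same order and names as `p`.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bhAdjust <- function(p) {
  x <- .checkP(p)
  out <- p.adjust(x, method = "BH")
  names(out) <- names(p)
  out
}
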