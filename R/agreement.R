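#' Two-rater agreement: accuracy and Cohen's kappa
#'
#' Compares two aligned category sequences (e.g. model labels against expert
#' annotations). Accuracy is the exact-match proportion; Cohen's kappa is
#' `(p_o - p_e) / (1 - p_e)` with the expected agreement `p_e` computed from
#' the product of the two raters' marginal proportions (unweighted, nominal
#' categories). When both raters are constant and identical (`p_e = 1`), the
#' kappa is reported as 1 with `degenerate = TRUE`.
#'
#' @param labels_a,labels_b character vectors of equal length (n >= 1).
#' @return list of class `mi_agreement`: `accuracy`, `kappa`, `n_items`,
#'   `degenerate`.
#' @export
#' @examples
#' agreement(c("change", "neutral"), c("change", "sustain"))
agreement <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop_validation("label sequences differ in length (%d vs %d)",
                    length(labels_a), length(labels_b))
  }
  n <- length(labels_a)
  if (n < 1L) stop_validation("need at least one item")
  labels_a <- as.character(labels_a)
  labels_b <- as.character(labels_b)
  cats <- sort(unique(c(labels_a, labels_b)))
  p_o <- mean(labels_a == labels_b)
  ma <- vapply(cats, function(k) mean(labels_a == k), numeric(1))
  mb <- vapply(cats, function(k) mean(labels_b == k), numeric(1))
  p_e <- sum(ma * mb)
  degenerate <- (1 - p_e) < .Machine$double.eps * 8
  kappa <- if (degenerate) 1.0 else (p_o - p_e) / (1 - p_e)
  structure(list(accuracy = p_o, kappa = kappa, n_items = n,
                 degenerate = degenerate),
            class = "mi_agreement")
}

#' @export
print.mi_agreement <- function(x, ...) {
  cat(sprintf("<mi_agreement> n = %d, accuracy = %.3f, Cohen's kappa = %.3f%s\n",
              x$n_items, x$accuracy, x$kappa,
              if (x$degenerate) " (degenerate: both raters constant)" else ""))
  invisible(x)
}

#' Fleiss' kappa for multi-rater categorical agreement
#'
#' Standard Fleiss kappa `(Pbar - Pbar_e) / (1 - Pbar_e)` on an items x
#' categories table of rating counts, every row summing to the number of
#' raters.
#'
#' @param counts numeric matrix, `counts[i, j]` = number of raters assigning
#'   item `i` to category `j`.
#' @param n_raters number of raters (>= 2); every row of `counts` must sum to
#'   it.
#' @return the kappa value in `[-1, 1]`.
#' @export
fleiss_kappa <- function(counts, n_raters) {
  counts <- as.matrix(counts)
  if (n_raters < 2) stop_validation("n_raters must be >= 2")
  rs <- rowSums(counts)
  if (any(rs != n_raters)) {
    stop_validation("row(s) %s do not sum to n_raters = %d",
                    paste(which(rs != n_raters), collapse = ","), n_raters)
  }
  N <- nrow(counts)
  P_i <- (rowSums(counts^2) - n_raters) / (n_raters * (n_raters - 1))
  P_bar <- mean(P_i)
  p_j <- colSums(counts) / (N * n_raters)
  P_e <- sum(p_j^2)
  if ((1 - P_e) < .Machine$double.eps * 8) return(1.0)
  (P_bar - P_e) / (1 - P_e)
}
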