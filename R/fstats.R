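#' f-statistics as scalar products in allele-frequency space
#'
#' The three classical f-statistics, all normalized as means over the s
#' SNPs of the panel:
#' \describe{
#'   \item{f2(a, b)}{`mean((p_a - p_b)^2)` — the squared Euclidean distance
#'     (per SNP) between two populations; always >= 0.}
#'   \item{f3(a, b; x)}{`mean((p_x - p_a) * (p_x - p_b))` — the scalar
#'     product of the two difference vectors at vertex x; a negative value
#'     is the classical admixture signal for x between a and b.}
#'   \item{f4(a, b; i, j)}{`mean((p_a - p_b) * (p_i - p_j))` — the drift
#'     shared by the two population pairs on a phylogeny.}
#' }
#' `f4_prime` is the renormalized statistic `s * f4(a,b;i,j) / f2(i,j)`:
#' the component of the (a - b) difference along the direction defined by
#' the auxiliary pair (i, j). It is the quantity that arises when the
#' configuration is projected onto the subspace spanned by auxiliary-pair
#' directions, and it is the coordinate used by the subspace estimators.
#'
#' Argument order matters: in `f3` the target/test population is the one
#' after the semicolon (the third argument here), and in `f4` the first
#' pair is the "left" difference. Swapping members of a pair flips the
#' sign of `f4`, which silently flips fitted mixing coefficients.
#'
#' @param panel A [frequency_panel].
#' @param a,b,target,i,j Population labels present in the panel.
#' @param tol Degenerate-pair guard for `f4_prime`: if `f2(i, j) <= tol`
#'   the pair defines no direction and an error is raised.
#' @return A single numeric value.
#' @examples
#' p <- frequency_panel(cbind(a = c(1, 1, 0), b = c(0, 0, 0), x = c(.5, .5, 0)))
#' f2(p, "a", "b")         # 2/3
#' f3(p, "a", "b", "x")    # -1/6: x midway between a and b
#' f4(p, "a", "b", "a", "b")  # equals f2(a, b)
#' @export
f2 <- function(panel, a, b) {
  mean((pop_vector(panel, a) - pop_vector(panel, b))^2)
}

#' @rdname f2
#' @export
f3 <- function(panel, a, b, target) {
  x <- pop_vector(panel, target)
  mean((x - pop_vector(panel, a)) * (x - pop_vector(panel, b)))
}

#' @rdname f2
#' @export
f4 <- function(panel, a, b, i, j) {
  mean((pop_vector(panel, a) - pop_vector(panel, b)) *
       (pop_vector(panel, i) - pop_vector(panel, j)))
}

#' @rdname f2
#' @export
f4_prime <- function(panel, a, b, i, j, tol = 1e-12) {
  denom <- f2(panel, i, j)
  if (denom <= tol) {
    stop(sprintf("degenerate auxiliary pair (%s, %s): f2 = %.3g <= tol; exclude the pair upstream",
                 i, j, denom), call. = FALSE)
  }
  n_snps(panel) * f4(panel, a, b, i, j) / denom
}
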