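#' Alpha diversity and richness estimates for one sample
#'
#' Computes, from a vector of OTU counts, the observed richness, Shannon
#' diversity (natural log by default), Simpson's index of diversity
#' (1 - D), the classic and bias-corrected Chao1 richness estimators, and
#' the abundance-based coverage estimator (ACE). Zero counts are dropped.
#'
#' Formulas, with \eqn{p_i = n_i/N}, \eqn{F_j} the number of OTUs seen
#' exactly j times and \eqn{S_{obs}} the observed OTU count:
#' \itemize{
#'   \item Shannon \eqn{H = -\sum_i p_i \log p_i}
#'   \item Simpson \eqn{1 - D = 1 - \sum_i p_i^2}
#'   \item classic Chao1 \eqn{S_{obs} + F_1^2/(2F_2)} (when \eqn{F_2 > 0};
#'     otherwise \eqn{S_{obs} + F_1(F_1-1)/2})
#'   \item bias-corrected Chao1 \eqn{S_{obs} + F_1(F_1-1)/(2(F_2+1))}
#'   \item ACE with rare OTUs those of count \eqn{\le} `rare_threshold`:
#'     sample coverage \eqn{C = 1 - F_1/N_{rare}}, squared coefficient of
#'     variation \eqn{\gamma^2 = \max(S_{rare}/C \cdot
#'     \sum_j j(j-1)F_j / (N_{rare}(N_{rare}-1)) - 1,\; 0)}, and
#'     \eqn{ACE = S_{abund} + S_{rare}/C + F_1 \gamma^2 / C}.
#' }
#' ACE is undefined (reported `NA` with a warning) when every rare read
#' is a singleton (\eqn{C = 0}); it equals \eqn{S_{obs}} when there are
#' no rare OTUs at all.
#'
#' @param counts Non-negative integer vector of per-OTU read counts
#'   (sum >= 1).
#' @param rare_threshold ACE rare/abundant cut; default 10 (the standard
#'   choice).
#' @param shannon_base Logarithm base for Shannon; default `exp(1)`.
#' @return One-row `data.frame`: `n_reads`, `observed_otus`, `shannon`,
#'   `simpson_1mD`, `chao1`, `chao1_bias_corrected`, `ace`,
#'   `rare_threshold`.
#' @examples
#' alpha_diversity(c(5, 5, 5, 5))   # H = log(4), 1-D = 0.75
#' alpha_diversity(c(1, 1, 2, 3))   # classic Chao1 = 6
#' @export
alpha_diversity <- function(counts, rare_threshold = 10L,
                            shannon_base = exp(1)) {
  stopifnot(is.numeric(counts), all(is.finite(counts)),
            all(counts >= 0), all(counts == round(counts)),
            rare_threshold >= 1)
  x <- counts[counts > 0]
  if (length(x) == 0L)
    stop("all counts are zero: diversity undefined")
  n <- sum(x)
  p <- x / n
  shannon <- -sum(p * log(p)) / log(shannon_base)
  simpson <- 1 - sum(p^2)
  s_obs <- length(x)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  chao1 <- if (f2 > 0) s_obs + f1^2 / (2 * f2) else s_obs + f1 * (f1 - 1) / 2
  chao1_bc <- s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  rare <- x <= rare_threshold
  s_rare <- sum(rare)
  s_abund <- s_obs - s_rare
  if (s_rare == 0L) {
    ace <- as.numeric(s_obs)
  } else {
    n_rare <- sum(x[rare])
    c_ace <- 1 - f1 / n_rare
    if (c_ace == 0) {
      warning("ACE undefined: every rare read is a singleton")
      ace <- NA_real_
    } else {
      fj <- tabulate(x[rare], nbins = rare_threshold)
      j <- seq_len(rare_threshold)
      gamma2 <- max(s_rare / c_ace * sum(j * (j - 1) * fj) /
                      (n_rare * (n_rare - 1)) - 1, 0)
      ace <- s_abund + s_rare / c_ace + f1 / c_ace * gamma2
    }
  }
  data.frame(n_reads = n, observed_otus = s_obs, shannon = shannon,
             simpson_1mD = simpson, chao1 = chao1,
             chao1_bias_corrected = chao1_bc, ace = ace,
             rare_threshold = as.integer(rare_threshold))
}

#' Per-sample alpha diversity for an OTU table
#'
#' @param table OTU count matrix (OTU x sample) from [build_otu_table()].
#' @param rare_threshold,shannon_base Passed to [alpha_diversity()].
#' @return `data.frame` with one row per sample, `sample_id` first.
#' @export
alpha_diversity_table <- function(table, rare_threshold = 10L,
                                  shannon_base = exp(1)) {
  stopifnot(is.matrix(table))
  rows <- lapply(colnames(table), function(s)
    cbind(sample_id = s,
          alpha_diversity(table[, s], rare_threshold, shannon_base)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
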