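#' Tissue preference of cell clusters (Ro/e)
#'
#' For each (cluster, tissue) cell of the contingency table, computes the
#' ratio of observed to expected cell numbers, Ro/e = O / E with
#' E = row total x column total / N, together with a two-sided chi-squared
#' test on the collapsed 2x2 table (this cluster vs the rest) x (this
#' tissue vs the rest), df = 1, no continuity correction by default.
#' Ro/e > 1 marks enrichment of the cluster in the tissue.
#'
#' @param ann annotation data.frame.
#' @param by column giving the cluster factor (default "cluster").
#' @param within column giving the tissue factor (default "tissue").
#' @param correct apply Yates continuity correction to the 2x2 test.
#' @param omnibus also compute a per-cluster omnibus chi-squared over all
#'   tissues (columns chi2_omnibus, p_omnibus, repeated within cluster).
#' @return data.frame(cluster, tissue, observed, expected, ro_e, chi2, p).
#' @export
ro_e_table <- function(ann, by = "cluster", within = "tissue",
                       correct = FALSE, omnibus = FALSE) {
  stopifnot(all(c(by, within) %in% names(ann)))
  tab <- table(ann[[by]], ann[[within]])
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    stop("need >= 2 clusters and >= 2 tissues with nonzero counts")
  }
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  ro_e <- tab / expected
  out <- expand.grid(cluster = rownames(tab), tissue = colnames(tab),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[order(out$cluster, out$tissue), , drop = FALSE]
  idx <- cbind(match(out$cluster, rownames(tab)),
               match(out$tissue, colnames(tab)))
  out$observed <- as.integer(tab[idx])
  out$expected <- expected[idx]
  out$ro_e <- as.numeric(ro_e[idx])
  stat <- mapply(function(i, j) {
    a <- tab[i, j]
    b <- sum(tab[i, ]) - a
    c_ <- sum(tab[, j]) - a
    d <- n - a - b - c_
    chisq_2x2(a, b, c_, d, correct = correct)
  }, idx[, 1], idx[, 2])
  out$chi2 <- stat
  out$p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  if (omnibus) {
    om <- t(vapply(rownames(tab), function(cl) {
      o <- tab[cl, ]
      e <- expected[cl, ]
      s <- sum((o - e)^2 / e)
      c(s, stats::pchisq(s, df = ncol(tab) - 1, lower.tail = FALSE))
    }, numeric(2)))
    out$chi2_omnibus <- om[match(out$cluster, rownames(tab)), 1]
    out$p_omnibus <- om[match(out$cluster, rownames(tab)), 2]
  }
  rownames(out) <- NULL
  out
}

# closed-form 2x2 chi-squared: N (ad - bc)^2 / (r1 r2 c1 c2)
chisq_2x2 <- function(a, b, c_, d, correct = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  c_ <- as.numeric(c_); d <- as.numeric(d)
  n <- a + b + c_ + d
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(0)
  num <- abs(a * d - b * c_)
  if (correct) num <- max(0, num - n / 2)
  n * num^2 / (r1 * r2 * c1 * c2)
}

#' Flag enriched / depleted / neutral (cluster, tissue) cells
#'
#' Enriched when Ro/e > `enrich_cut` and p < `alpha`; depleted when
#' Ro/e < 1 / `enrich_cut` and p < `alpha`; otherwise neutral. With the
#' default `enrich_cut = 1`, Ro/e exactly 1 is neutral regardless of p.
#'
#' @param tab output of [ro_e_table()].
#' @param enrich_cut Ro/e cut (>= 1).
#' @param alpha significance cut on the chi-squared p.
#' @return `tab` with a `preference` column added.
#' @export
preference_flags <- function(tab, enrich_cut = 1, alpha = 0.05) {
  if (enrich_cut < 1) stop("enrich_cut must be >= 1")
  pref <- rep("neutral", nrow(tab))
  pref[tab$ro_e > enrich_cut & tab$p < alpha] <- "enriched"
  pref[tab$ro_e < 1 / enrich_cut & tab$p < alpha] <- "depleted"
  tab$preference <- pref
  tab
}
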