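# Independent oracles used across test files. These deliberately avoid the
# package's own code paths.

# population variance of a point set (for window-placement checks)
oracle_var <- function(pts) mean((pts - mean(pts))^2)

# exhaustive pair minimisation with lexicographic tie-break
oracle_best_pair <- function(s, e, cand) {
  cand <- sort(cand)
  best <- NULL
  best_val <- Inf
  for (i in seq_along(cand)[-length(cand)]) {
    for (j in (i + 1):length(cand)) {
      v <- oracle_var(c(s, cand[i], cand[j], e))
      if (v < best_val) {
        best_val <- v
        best <- c(cand[i], cand[j])
      }
    }
  }
  best
}

oracle_best_single <- function(s, e, cand) {
  cand <- sort(cand)
  vals <- vapply(cand, function(x) oracle_var(c(s, x, e)), numeric(1))
  cand[which.min(vals)]
}

# exact Hardy-Weinberg p-value by full enumeration with plain factorials
# (valid for n <= ~80); conditions on the observed allele count
oracle_hwe <- function(naa, nab, nbb) {
  n <- naa + nab + nbb
  na_ct <- 2 * naa + nab                  # allele A count
  hets <- seq(na_ct %% 2, min(na_ct, 2 * n - na_ct), by = 2)
  probs <- vapply(hets, function(h) {
    n_a_hom <- (na_ct - h) / 2
    n_b_hom <- n - h - n_a_hom
    2^h * factorial(n) /
      (factorial(n_a_hom) * factorial(h) * factorial(n_b_hom))
  }, numeric(1))
  probs <- probs / sum(probs)
  p_obs <- probs[match(nab, hets)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-9)]))
}

# two-population Weir-Cockerham Fst via an ANOVA on expanded 0/1 allele
# vectors (textbook mean-squares route)
oracle_wc_fst <- function(alt1, n1, alt2, n2) {
  y <- c(rep(1, alt1), rep(0, n1 - alt1), rep(1, alt2), rep(0, n2 - alt2))
  pop <- factor(rep(c("a", "b"), c(n1, n2)))
  ms <- suppressWarnings(anova(lm(y ~ pop)))[["Mean Sq"]]
  msb <- ms[1]
  msw <- ms[2]
  nc <- (n1 + n2) - (n1^2 + n2^2) / (n1 + n2)
  (msb - msw) / (msb + (nc - 1) * msw)
}

# best label agreement between a clustering and truth over permutations
label_agreement <- function(cluster, truth) {
  k <- length(unique(truth))
  perms <- if (k == 3) {
    list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
         c(3, 2, 1))
  } else {
    stop("only k = 3 supported")
  }
  max(vapply(perms, function(p) mean(p[cluster] == truth), numeric(1)))
}

# small deterministic candidate tibble for io tests
toy_candidates <- function(n, genome, seed = 1) {
  withr::with_seed(seed, {
    chrom <- sample(genome$chrom, n, replace = TRUE)
    len <- setNames(genome$length, genome$chrom)
    pos <- vapply(chrom, function(cn) sample.int(len[[cn]], 1), numeric(1))
    keep <- !duplicated(paste(chrom, pos))
    chrom <- chrom[keep]; pos <- pos[keep]
    nt <- c("A", "C", "G", "T")
    ref <- sample(nt, length(pos), replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(nt, r), 1), character(1))
    grp <- sample(c("resequencing", "gwas", "candidate_gene", "rfi", "snpdb"),
                  length(pos), replace = TRUE)
    tibble::tibble(
      snp_id = paste0("s", seq_along(pos)), chrom = chrom, pos = pos,
      ref = ref, alt = unname(alt), group = grp,
      priority = snpanel:::group_priority(grp),
      validated = grp == "snpdb", is_indel = FALSE,
      score = round(runif(length(pos)), 4))
  })
}
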