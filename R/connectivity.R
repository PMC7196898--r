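# Bombardment-assay connectivity statistics.

#' Normalize counts to the within-genotype mock mean
#'
#' Adds a \code{normalized_count} column: \code{n_cells} divided by the mean
#' mock count of the same genotype, so mock normalized counts average 1
#' within each genotype.
#'
#' @param table bombardment table (genotype, treatment, replicate, n_cells).
#' @param mockLabel treatment level used as the baseline (default "mock").
#' @return the table with \code{normalized_count} added.
#' @export
normalizeCounts <- function(table, mockLabel = "mock") {
  validateBombardmentTable(table)
  out <- table
  out$normalized_count <- NA_real_
  for (g in unique(table$genotype)) {
    inG <- table$genotype == g
    mock <- table$n_cells[inG & table$treatment == mockLabel]
    if (length(mock) == 0)
      stop("missing mock baseline for genotype: ", g)
    out$normalized_count[inG] <- table$n_cells[inG] / mean(mock)
  }
  out
}

#' Within-genotype mock-vs-treated comparison
#'
#' Two-sided Mann-Whitney rank-sum test (default) or a seeded permutation
#' test on the difference of mean normalized counts, pooling sites as the
#' per-site plots do. A replicate-stratified permutation (shuffling
#' treatment labels within replicates) is available.
#'
#' @param table normalized table from \code{\link{normalizeCounts}}.
#' @param genotype genotype to test.
#' @param test "mann_whitney" or "permutation".
#' @param treatment treated level; defaults to the single non-mock level.
#' @param mockLabel baseline treatment label.
#' @param nPerm permutation count (default 1e4).
#' @param seed RNG seed for permutation.
#' @param stratifyByReplicate permute within replicates only.
#' @return list: genotype, groups, n, statistic, p_value, stars.
#' @export
compareTreatment <- function(table, genotype,
                             test = c("mann_whitney", "permutation"),
                             treatment = NULL, mockLabel = "mock",
                             nPerm = 10000L, seed = 1,
                             stratifyByReplicate = FALSE) {
  test <- match.arg(test)
  if (!"normalized_count" %in% names(table))
    stop("table must be normalized first (normalizeCounts)")
  sub <- table[table$genotype == genotype, ]
  if (nrow(sub) == 0) stop("no rows for genotype: ", genotype)
  lev <- setdiff(unique(sub$treatment), mockLabel)
  if (is.null(treatment)) {
    if (length(lev) != 1)
      stop("specify the treated level; found: ", paste(lev, collapse = ", "))
    treatment <- lev
  }
  a <- sub$normalized_count[sub$treatment == mockLabel]
  b <- sub$normalized_count[sub$treatment == treatment]
  if (length(a) < 5 || length(b) < 5)
    stop("insufficient data: both treatment groups need n >= 5")
  if (test == "mann_whitney") {
    wt <- suppressWarnings(wilcox.test(b, a, exact = FALSE))
    stat <- unname(wt$statistic); p <- wt$p.value
  } else {
    obs <- mean(b) - mean(a)
    pool <- c(a, b)
    grp <- rep(c(0L, 1L), c(length(a), length(b)))
    strata <- if (stratifyByReplicate)
      c(sub$replicate[sub$treatment == mockLabel],
        sub$replicate[sub$treatment == treatment]) else rep(1L, length(pool))
    rng <- localRNG(seed)
    perm <- rng(vapply(seq_len(nPerm), function(i) {
      ng <- grp
      for (s in unique(strata)) {
        k <- strata == s
        ng[k] <- sample(grp[k])
      }
      mean(pool[ng == 1L]) - mean(pool[ng == 0L])
    }, numeric(1)))
    stat <- obs
    p <- (1 + sum(abs(perm) >= abs(obs))) / (nPerm + 1)
  }
  list(genotype = genotype, groups = c(mockLabel, treatment),
       n = c(length(a), length(b)), statistic = stat, p_value = p,
       stars = pStars(p))
}

#' Notched boxplot summary statistics
#'
#' Quartiles by linear interpolation (type 7); whiskers at the most extreme
#' data within 1.5 IQR beyond the quartiles; notches at
#' median +- 1.58 IQR / sqrt(n), the standard approximate 95 percent CI of
#' the median.
#'
#' @param values numeric vector, n >= 5.
#' @return list: median, q1, q3, whiskerLow, whiskerHigh, notchLow,
#'   notchHigh, n.
#' @export
boxplotSummary <- function(values) {
  n <- length(values)
  if (n < 5) stop("insufficient data: need n >= 5")
  q <- quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lowFence <- q[1] - 1.5 * iqr
  highFence <- q[3] + 1.5 * iqr
  inLow <- values[values >= lowFence]
  inHigh <- values[values <= highFence]
  notch <- 1.58 * iqr / sqrt(n)
  list(median = q[2], q1 = q[1], q3 = q[3],
       whiskerLow = min(inLow), whiskerHigh = max(inHigh),
       notchLow = q[2] - notch, notchHigh = q[2] + notch, n = n)
}

# greedy insert-and-absorb compact letter display from a pairwise
# significance matrix; groups ordered by mean descending get letters first
compactLetters <- function(sig, meansDesc) {
  g <- rownames(sig)
  cols <- list(g)
  for (i in seq_len(length(g) - 1)) for (j in (i + 1):length(g)) {
    if (!sig[g[i], g[j]]) next
    k <- 1
    while (k <= length(cols)) {
      cl <- cols[[k]]
      if (g[i] %in% cl && g[j] %in% cl) {
        cols[[k]] <- setdiff(cl, g[i])
        cols[[length(cols) + 1L]] <- setdiff(cl, g[j])
      }
      k <- k + 1
    }
    # absorb: drop columns that are subsets of another
    keep <- rep(TRUE, length(cols))
    for (a in seq_along(cols)) for (b in seq_along(cols)) {
      if (a == b || !keep[a]) next
      if (all(cols[[a]] %in% cols[[b]]) &&
          (length(cols[[a]]) < length(cols[[b]]) || a > b && keep[b] &&
             setequal(cols[[a]], cols[[b]])))
        keep[a] <- FALSE
    }
    cols <- cols[keep]
  }
  # letter order: by the best-ranked (highest mean) member of each column
  rank1 <- vapply(cols, function(cl) min(match(cl, meansDesc)), numeric(1))
  cols <- cols[order(rank1)]
  letters_ <- letters[seq_along(cols)]
  out <- vapply(meansDesc, function(gr) {
    paste0(letters_[vapply(cols, function(cl) gr %in% cl, logical(1))],
           collapse = "")
  }, character(1))
  names(out) <- meansDesc
  out
}

#' One-way ANOVA with Tukey HSD and a compact letter display
#'
#' Fits a one-way ANOVA across the groups, computes Tukey HSD adjusted
#' pairwise p-values, and assigns compact letters by greedy
#' insert-and-absorb so that groups sharing a letter are not significantly
#' different at \code{alpha}. Letters are deterministic: groups are
#' processed in order of decreasing mean.
#'
#' @param groups named list, label -> numeric values (>= 2 groups, each
#'   n >= 3).
#' @param alpha significance level (default 0.01).
#' @return list: letters (named by group, mean-descending order), pairwise
#'   (data.frame of comparisons), anovaP, means.
#' @export
anovaTukeyLetters <- function(groups, alpha = 0.01) {
  if (length(groups) < 2) stop("need at least two groups")
  if (any(vapply(groups, length, integer(1)) < 3))
    stop("insufficient data: every group needs n >= 3")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, integer(1)))))
  if (var(df$value) == 0) {
    # all observations identical: nothing distinguishable
    meansDesc <- names(sort(vapply(groups, mean, numeric(1)),
                            decreasing = TRUE))
    lt <- setNames(rep("a", length(groups)), meansDesc)
    return(list(letters = lt, pairwise = NULL, anovaP = 1,
                means = vapply(groups, mean, numeric(1))))
  }
  fit <- aov(value ~ group, data = df)
  anovaP <- summary(fit)[[1]][["Pr(>F)"]][1]
  tk <- TukeyHSD(fit)$group
  pw <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                   p_adj = tk[, "p adj"], row.names = NULL,
                   stringsAsFactors = FALSE)
  nm <- names(groups)
  sig <- matrix(FALSE, length(nm), length(nm), dimnames = list(nm, nm))
  for (k in seq_len(nrow(pw))) {
    pair <- strsplit(pw$comparison[k], "-", fixed = TRUE)[[1]]
    s <- pw$p_adj[k] < alpha
    sig[pair[1], pair[2]] <- s
    sig[pair[2], pair[1]] <- s
  }
  meansDesc <- names(sort(vapply(groups, mean, numeric(1)), decreasing = TRUE))
  lt <- compactLetters(sig, meansDesc)
  list(letters = lt, pairwise = pw, anovaP = anovaP,
       means = vapply(groups, mean, numeric(1)))
}
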