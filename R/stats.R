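#' Construct a proportion sample
#'
#' A proportion `p` observed over `n` sequences, the unit of the two-sample
#' proportion z-test.
#'
#' @param p Proportion in `[0, 1]`.
#' @param n Number of sequences (>= 1).
#' @return Object of class `proportion_sample`.
#' @export
proportion_sample <- function(p, n) {
  if (p < 0 || p > 1) stop("p must lie in [0,1]")
  if (n < 1) stop("n must be >= 1")
  structure(list(p = p, n = n), class = "proportion_sample")
}

#' Two-sample proportion z-test
#'
#' Compares two proportions p_T (over n_T sequences) and p_B (over n_B
#' sequences) with the pooled-proportion z statistic:
#' p_hat = (n_T p_T + n_B p_B) / (n_T + n_B) and
#' Z = (p_T - p_B) / sqrt(p_hat (1 - p_hat) (1/n_T + 1/n_B)),
#' with a two-sided p-value from the standard normal distribution. When the
#' pooled proportion is 0 or 1 the statistic is undefined and a degenerate
#' result with p = 1 is returned, flagged.
#'
#' @param t,b [proportion_sample()] objects (e.g. tumor and blood).
#' @return A list with `statistic` (Z), `p_value`, `method`, `degenerate`.
#' @export
proportion_ztest <- function(t, b) {
  stopifnot(inherits(t, "proportion_sample"), inherits(b, "proportion_sample"))
  p_hat <- (t$n * t$p + b$n * b$p) / (t$n + b$n)
  if (p_hat <= 0 || p_hat >= 1) {
    return(list(statistic = NA_real_, p_value = 1, method = "proportion_ztest",
                degenerate = TRUE))
  }
  z <- (t$p - b$p) / sqrt(p_hat * (1 - p_hat) * (1 / t$n + 1 / b$n))
  list(statistic = z, p_value = 2 * stats::pnorm(-abs(z)),
       method = "proportion_ztest", degenerate = FALSE)
}

#' Permutation test for a two-group ratio statistic
#'
#' Compares an observed two-group statistic (by default the ratio of group
#' means) against a null distribution obtained by randomly reassigning the
#' group labels over the same sequences (`n_perm` draws). Two-sidedness is
#' implemented as absolute deviation from the null-distribution mean, and
#' the empirical p-value uses the add-one correction
#' p = (1 + #(|null - mean(null)| >= |observed - mean(null)|)) / (n_perm + 1),
#' so p is never exactly zero.
#'
#' @param group_labels Vector with exactly two distinct labels.
#' @param values Numeric vector, same length.
#' @param statistic Function `(values, labels) -> scalar`; the default is
#'   mean(first group) / mean(second group), groups in label sort order.
#' @param n_perm Number of permutations (default 1000).
#' @param seed RNG seed.
#' @return List with `statistic` (observed), `p_value`, `null` (the
#'   permuted statistics), `method`, `seed`, `n_perm`.
#' @export
permutation_ratio_test <- function(group_labels, values, statistic = NULL,
                                   n_perm = 1000, seed = 1) {
  labs <- sort(unique(group_labels))
  if (length(labs) != 2) stop("exactly two groups required")
  if (is.null(statistic)) {
    statistic <- function(v, l) mean(v[l == labs[1]]) / mean(v[l == labs[2]])
  }
  obs <- statistic(values, group_labels)
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) {
    statistic(values, sample(group_labels))
  }, numeric(1))
  center <- mean(null)
  p <- (1 + sum(abs(null - center) >= abs(obs - center))) / (n_perm + 1)
  list(statistic = obs, p_value = p, null = null,
       method = "permutation_ratio_test", seed = seed, n_perm = n_perm)
}

#' Bootstrap percentile confidence interval
#'
#' Percentile interval of a statistic over `n_boot` resamples with
#' replacement; `level = 0` degenerates to the point estimate.
#'
#' @param values Numeric vector (length >= 2).
#' @param statistic Function of a numeric vector; default [mean()].
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed RNG seed.
#' @return List with `estimate`, `lower`, `upper`, `level`, `seed`,
#'   `n_boot`.
#' @export
bootstrap_ci <- function(values, statistic = mean, n_boot = 1000,
                         level = 0.95, seed = 1) {
  if (length(values) < 2) stop("bootstrap_ci requires at least 2 values")
  set.seed(seed)
  n <- length(values)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
  boots <- apply(idx, 2, function(i) statistic(values[i]))
  est <- statistic(values)
  alpha <- (1 - level) / 2
  q <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE, type = 7)
  list(estimate = est, lower = q[1], upper = q[2], level = level,
       seed = seed, n_boot = n_boot)
}

#' Gene-usage frequency tables with compartment comparisons
#'
#' Relative frequencies of single genes, gene pairs, or gene x isotype
#' combinations per sample and compartment (frequencies sum to 1 within
#' each group), with optional two-sample proportion z-tests per key across
#' two compartments, reported raw and Benjamini-Hochberg adjusted.
#'
#' @param ann Annotation tibble.
#' @param key One of `"v"`, `"j"`, `"d"`, `"vj"`, `"vd"`, `"dj"`,
#'   `"v_isotype"`.
#' @param by Grouping column (default `"compartment"`).
#' @param test Run compartment-wise z-tests (requires exactly two groups).
#' @return List with `frequencies` and (when tested) `tests`.
#' @export
usage_tables <- function(ann, key = "v", by = "compartment", test = FALSE) {
  gene_of <- function(col) sub("\\*.*$", "", ann[[col]])
  keyval <- switch(
    key,
    v = gene_of("v_call"),
    j = gene_of("j_call"),
    d = gene_of("d_call"),
    vj = paste(gene_of("v_call"), gene_of("j_call"), sep = "|"),
    vd = paste(gene_of("v_call"), gene_of("d_call"), sep = "|"),
    dj = paste(gene_of("d_call"), gene_of("j_call"), sep = "|"),
    v_isotype = paste(gene_of("v_call"), ann$c_call, sep = "|"),
    stop("unknown key: ", key))
  df <- tibble(group = ann[[by]], key = keyval)
  df <- df[!is.na(df$key) & !grepl("NA", df$key, fixed = TRUE), ]
  freq <- df %>%
    group_by(.data$group, .data$key) %>%
    summarise(count = n(), .groups = "drop_last") %>%
    mutate(frequency = .data$count / sum(.data$count),
           n_group = sum(.data$count)) %>%
    ungroup()
  out <- list(frequencies = freq)
  if (test) {
    grps <- unique(freq$group)
    if (length(grps) != 2) stop("usage tests require exactly two groups")
    keys <- unique(freq$key)
    tests <- dplyr::bind_rows(lapply(keys, function(k) {
      f1 <- freq[freq$group == grps[1] & freq$key == k, ]
      f2 <- freq[freq$group == grps[2] & freq$key == k, ]
      n1 <- freq$n_group[freq$group == grps[1]][1]
      n2 <- freq$n_group[freq$group == grps[2]][1]
      p1 <- if (nrow(f1)) f1$frequency else 0
      p2 <- if (nrow(f2)) f2$frequency else 0
      zt <- proportion_ztest(proportion_sample(p1, n1),
                             proportion_sample(p2, n2))
      tibble(key = k, p1 = p1, p2 = p2, z = zt$statistic,
             p_value = zt$p_value)
    }))
    tests$p_adj <- stats::p.adjust(tests$p_value, method = "BH")
    out$tests <- tests
  }
  out
}

#' Per-sample, per-isotype repertoire summary
#'
#' The four headline repertoire quantities per sample and isotype on a
#' collapsed unique-sequence set: isotype distribution (fraction of the
#' sample), percent unproductive sequences, mean percent of total V
#' mutations, and mean replacement/total mutation ratio R/(R+S) (0 by
#' convention for unmutated sequences). Groups with fewer than 5 sequences
#' are flagged `low_n`.
#'
#' @param ann Collapsed annotation tibble (heavy chains).
#' @return Tibble, one row per sample x isotype.
#' @export
repertoire_summary <- function(ann) {
  h <- ann[ann$chain == "heavy" & !is.na(ann$c_call), ]
  h$r_total <- ifelse(
    (h$s_fr + h$s_cdr + h$r_fr + h$r_cdr) > 0,
    (h$r_fr + h$r_cdr) / (h$s_fr + h$s_cdr + h$r_fr + h$r_cdr), 0)
  h %>%
    group_by(.data$sample_id) %>%
    mutate(n_sample = n()) %>%
    group_by(.data$sample_id, isotype = .data$c_call) %>%
    summarise(
      n = n(),
      fraction_of_sample = n() / .data$n_sample[1],
      pct_unproductive = 100 * mean(!.data$productive, na.rm = TRUE),
      pct_total_mutations = mean(.data$pct_mut, na.rm = TRUE),
      r_total_ratio = mean(.data$r_total, na.rm = TRUE),
      low_n = n() < 5,
      .groups = "drop")
}
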