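#' @title Likert rating analysis
#' @name rating
#' @description
#' Summaries and nonparametric tests for long-format Likert rating datasets
#' from the 6-condition flanker rating design: per-condition and
#' per-participant means, an exact Wilcoxon signed-rank test (full
#' enumeration of sign assignments via the shift algorithm, midranks for
#' ties, discard or Pratt handling of zeros), and a within-person
#' consistency metric (mean absolute pairwise difference between ratings of
#' the same condition).
NULL

#' Condition codes of the rating design
#' @return `c("A", ..., "F")`: A = long, B = gapped, C = long + inward,
#'   D = gapped + inward, E = long + outward, F = gapped + outward.
#' @export
rating_conditions <- function() c("A", "B", "C", "D", "E", "F")

#' Map rating-design condition codes to model condition names
#' @param code Vector of codes in `A..F`.
#' @return Model condition names as in [condition_names()].
#' @export
rating_code_to_condition <- function(code) {
  map <- c(A = "LONG", B = "GAPPED", C = "LONG_INWARD", D = "GAPPED_INWARD",
           E = "LONG_OUTWARD", F = "GAPPED_OUTWARD")
  unname(map[code])
}

validate_ratings <- function(data) {
  need <- c("participant", "condition", "side", "repetition", "rating")
  if (!all(need %in% names(data))) {
    stop("rating data must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(data$rating %in% 1:5)) stop("ratings must be integers 1..5")
  if (!all(data$condition %in% rating_conditions())) {
    stop("conditions must be codes A..F")
  }
  invisible(data)
}

#' Per-condition and per-participant rating summaries
#'
#' @param data Long-format rating data frame with columns `participant`,
#'   `condition` (codes A..F), `side`, `repetition`, `rating` (1..5).
#' @param quiet Suppress the partial-dataset message.
#' @return A `rating_summary`: list with `condition_means` (grand mean over
#'   all ratings per condition; `NA` for an empty condition),
#'   `participant_means` (participant x condition matrix of cell means),
#'   `n_per_cell`, and `complete` (`TRUE` iff every participant has 4
#'   ratings per condition).
#' @export
condition_summary <- function(data, quiet = FALSE) {
  validate_ratings(data)
  conds <- rating_conditions()
  parts <- sort(unique(data$participant))
  pm <- matrix(NA_real_, length(parts), length(conds),
               dimnames = list(as.character(parts), conds))
  np <- matrix(0L, length(parts), length(conds),
               dimnames = dimnames(pm))
  agg <- tapply(data$rating,
                list(factor(data$participant, parts),
                     factor(data$condition, conds)), mean)
  cnt <- tapply(data$rating,
                list(factor(data$participant, parts),
                     factor(data$condition, conds)), length)
  pm[] <- agg
  np[] <- ifelse(is.na(cnt), 0L, cnt)
  cm <- tapply(data$rating, factor(data$condition, conds), mean)
  observed <- conds %in% unique(data$condition)
  complete <- all(observed) && all(np == 4L)
  if (!complete && !quiet) {
    message("partial rating dataset: not every participant x condition ",
            "cell has 4 ratings")
  }
  structure(list(condition_means = as.numeric(cm), conditions = conds,
                 participant_means = pm, n_per_cell = np,
                 complete = complete),
            class = "rating_summary")
}

#' @export
print.rating_summary <- function(x, ...) {
  cat("<rating_summary>", nrow(x$participant_means), "participants",
      if (!x$complete) "(partial)" else "", "\n")
  print(round(stats::setNames(x$condition_means, x$conditions), 3))
  invisible(x)
}

# exact null distribution of 2*W+ for given (possibly tied) ranks, via the
# shift algorithm: counts[w + 1] = number of sign assignments with 2*W+ = w
signed_rank_counts <- function(ranks2) {
  total <- sum(ranks2)
  counts <- numeric(total + 1)
  counts[1] <- 1
  for (r in ranks2) {
    shifted <- c(numeric(r), counts[seq_len(total + 1 - r)])
    counts <- counts + shifted
  }
  counts
}

#' Exact Wilcoxon signed-rank test
#'
#' Tests paired samples via the signed ranks of the differences. Absolute
#' differences receive midranks; zeros are discarded (classical) or kept for
#' ranking but excluded from the sums (Pratt). The exact p-value enumerates
#' all `2^n` sign assignments (computed by the shift algorithm, which gives
#' identical counts); a normal approximation with tie-corrected variance and
#' continuity correction is used above `exact_limit`.
#'
#' The reported `statistic` follows the common convention W = the smaller of
#' the positive- and negative-rank sums; p-values are computed from the
#' positive-rank sum `w_plus`.
#'
#' @param x,y Paired numeric vectors (`y` may be omitted to test
#'   differences `x` against zero).
#' @param zero_policy `"discard"` or `"pratt"`.
#' @param sided `"two"`, `"less"` or `"greater"` (for the location of
#'   `x - y`).
#' @param method `"auto"`, `"exact"` or `"normal"`.
#' @param exact_limit Largest `n` for which `"auto"` uses the exact
#'   distribution.
#' @return A `wilcoxon_result`: `statistic` (smaller rank sum), `w_plus`,
#'   `p_value`, `n_effective`, `method`, `zero_policy`, `sided`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL,
                                 zero_policy = c("discard", "pratt"),
                                 sided = c("two", "less", "greater"),
                                 method = c("auto", "exact", "normal"),
                                 exact_limit = 25L) {
  zero_policy <- match.arg(zero_policy)
  sided <- match.arg(sided)
  method <- match.arg(method)
  d <- if (is.null(y)) as.numeric(x) else {
    if (length(x) != length(y)) stop("x and y must have equal length")
    as.numeric(x) - as.numeric(y)
  }
  d <- d[!is.na(d)]
  if (length(d) == 0L) stop("no non-missing differences")
  nonzero <- d != 0
  if (!any(nonzero)) {
    warning("all differences are zero; degenerate result")
    return(structure(list(statistic = 0, w_plus = 0, p_value = 1,
                          n_effective = 0L, method = "degenerate",
                          zero_policy = zero_policy, sided = sided),
                     class = "wilcoxon_result"))
  }
  if (zero_policy == "discard") {
    dd <- d[nonzero]
    r <- rank(abs(dd))
  } else {
    r_all <- rank(abs(d))
    dd <- d[nonzero]
    r <- r_all[nonzero]
  }
  n_eff <- length(dd)
  w_plus <- sum(r[dd > 0])
  w_minus <- sum(r) - w_plus
  statistic <- min(w_plus, w_minus)
  use_exact <- method == "exact" || (method == "auto" && n_eff <= exact_limit)
  if (use_exact) {
    ranks2 <- as.integer(round(2 * r))
    counts <- signed_rank_counts(ranks2)
    tot <- 2^n_eff
    w2 <- round(2 * w_plus)
    p_le <- sum(counts[seq_len(w2 + 1)]) / tot
    p_ge <- sum(counts[(w2 + 1):length(counts)]) / tot
    meth <- "exact_enumeration"
  } else {
    mu <- sum(r) / 2
    sigma <- sqrt(sum(r^2) / 4)
    # continuity correction of half the smallest rank step (0.5 on 2r scale)
    p_le <- stats::pnorm(w_plus + 0.25, mu, sigma)
    p_ge <- stats::pnorm(w_plus - 0.25, mu, sigma, lower.tail = FALSE)
    meth <- "normal_approx"
  }
  p <- switch(sided,
              less = p_le,
              greater = p_ge,
              two = min(1, 2 * min(p_le, p_ge)))
  structure(list(statistic = statistic, w_plus = w_plus, p_value = p,
                 n_effective = n_eff, method = meth,
                 zero_policy = zero_policy, sided = sided),
            class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat("Wilcoxon signed-rank test (", x$method, ", zeros: ", x$zero_policy,
      ")\n", sep = "")
  cat("  statistic (smaller signed-rank sum) =", x$statistic,
      " n =", x$n_effective, "\n")
  cat("  ", x$sided, "-sided p = ", signif(x$p_value, 4), "\n", sep = "")
  invisible(x)
}

#' Within-person rating consistency
#'
#' For every participant x condition cell with at least two ratings, the
#' mean absolute pairwise difference among the cell's ratings; cell values
#' are averaged within participant and then across participants. Larger
#' values mean less consistent trial-to-trial percepts.
#'
#' @param data Long-format rating data (see [condition_summary()]).
#' @return List with `value` (the consistency metric), `per_participant`,
#'   and `n_singleton` (cells excluded for having < 2 ratings).
#' @export
within_consistency <- function(data) {
  validate_ratings(data)
  parts <- sort(unique(data$participant))
  n_singleton <- 0L
  per_part <- vapply(parts, function(p) {
    sub <- data[data$participant == p, ]
    cell_vals <- c()
    for (cond in unique(sub$condition)) {
      rr <- sub$rating[sub$condition == cond]
      if (length(rr) < 2L) {
        n_singleton <<- n_singleton + 1L
        next
      }
      prs <- utils::combn(rr, 2)
      cell_vals <- c(cell_vals, mean(abs(prs[1, ] - prs[2, ])))
    }
    if (length(cell_vals) == 0L) NA_real_ else mean(cell_vals)
  }, numeric(1))
  list(value = mean(per_part, na.rm = TRUE),
       per_participant = stats::setNames(per_part, as.character(parts)),
       n_singleton = n_singleton)
}

#' Paired per-participant condition means for two conditions
#' @param data Long-format rating data.
#' @param c1,c2 Condition codes.
#' @return Data frame with `participant`, `mean1`, `mean2` for participants
#'   observed in both conditions.
#' @export
paired_condition_means <- function(data, c1, c2) {
  s <- condition_summary(data, quiet = TRUE)
  m1 <- s$participant_means[, c1]
  m2 <- s$participant_means[, c2]
  keep <- !is.na(m1) & !is.na(m2)
  data.frame(participant = rownames(s$participant_means)[keep],
             mean1 = m1[keep], mean2 = m2[keep])
}

#' Full rating-dataset analysis report
#'
#' Summarizes the dataset and runs the signed-rank comparison between two
#' conditions. The default pairing unit is the per-participant condition
#' mean; per-trial pairing (sorted within cell) is available.
#'
#' @param data Long-format rating data.
#' @param test_pair Length-2 character vector of condition codes to compare.
#' @param pairing `"participant_means"` or `"trials"`.
#' @param ... Passed to [wilcoxon_signed_rank()].
#' @return List with `summary`, `wilcoxon`, `consistency`.
#' @export
analyze_ratings <- function(data, test_pair = c("A", "D"),
                            pairing = c("participant_means", "trials"), ...) {
  pairing <- match.arg(pairing)
  s <- condition_summary(data)
  if (pairing == "participant_means") {
    pp <- paired_condition_means(data, test_pair[1], test_pair[2])
    w <- wilcoxon_signed_rank(pp$mean1, pp$mean2, ...)
  } else {
    grab <- function(cc) {
      sub <- data[data$condition == cc, ]
      sub <- sub[order(sub$participant, sub$side, sub$repetition), ]
      sub$rating
    }
    w <- wilcoxon_signed_rank(grab(test_pair[1]), grab(test_pair[2]), ...)
  }
  list(summary = s, wilcoxon = w, consistency = within_consistency(data))
}

#' Write/read rating data as CSV
#'
#' Long format with header `participant,condition,side,repetition,rating`.
#'
#' @param data Rating data frame.
#' @param path CSV path.
#' @return `path` invisibly (write) or the data frame (read).
#' @export
write_ratings_csv <- function(data, path) {
  validate_ratings(data)
  utils::write.csv(data[c("participant", "condition", "side",
                          "repetition", "rating")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ratings_csv
#' @export
read_ratings_csv <- function(path) {
  data <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_ratings(data)
  data
}
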