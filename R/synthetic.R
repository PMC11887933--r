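#' @title Synthetic ordinal rating generator
#' @name synthetic
#' @description
#' Generates Likert rating datasets with the rating study's design (15
#' participants x 6 conditions x 2 sides x 2 repetitions, ratings 1..5)
#' from a thresholded-Gaussian (cumulative-link) latent model: latent value
#' = condition mean + participant effect + trial noise, discretized by four
#' strictly increasing cutpoints. Every analysis stage is thereby testable
#' without any external data.
NULL

#' Parameters of the latent rating model
#'
#' Default condition means follow the qualitative pattern of the rating
#' results: the gapped conditions (B, D, F) and the long-with-inward-inducer
#' condition (C) sit high (latent 4, "three separate gratings"), while the
#' long conditions A and E sit low (latent 2, "one long grating"). These
#' defaults are illustrative of the reported pattern, not fitted values.
#' The default trial noise is large, emulating the reported within-person
#' inconsistency of roughly two rating points between repeats.
#'
#' @param condition_latent_means Named numeric vector over codes A..F.
#' @param participant_sd SD of the Gaussian participant effect.
#' @param trial_sd SD of the Gaussian trial noise.
#' @param cutpoints Four strictly increasing cutpoints mapping latent values
#'   to ratings 1..5; the defaults make integer latent means map to their
#'   own rating.
#' @param n_participants Number of participants.
#' @param seed Integer seed; a fixed seed gives a bit-identical dataset.
#' @return An object of class `rating_model_params`.
#' @export
rating_model_params <- function(condition_latent_means = c(A = 2, B = 4, C = 4,
                                                           D = 4, E = 2, F = 4),
                                participant_sd = 0.5,
                                trial_sd = 1.7,
                                cutpoints = c(1.5, 2.5, 3.5, 4.5),
                                n_participants = 15L,
                                seed = 1L) {
  if (length(cutpoints) != 4L || any(diff(cutpoints) <= 0)) {
    stop("cutpoints must be 4 strictly increasing values")
  }
  stopifnot(setequal(names(condition_latent_means), rating_conditions()),
            participant_sd >= 0, trial_sd >= 0, n_participants >= 1)
  structure(list(
    condition_latent_means = condition_latent_means[rating_conditions()],
    participant_sd = participant_sd, trial_sd = trial_sd,
    cutpoints = cutpoints, n_participants = as.integer(n_participants),
    seed = as.integer(seed)), class = "rating_model_params")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

latent_to_rating <- function(latent, cutpoints) {
  findInterval(latent, cutpoints) + 1L
}

#' Generate a synthetic rating dataset
#'
#' Every participant rates every condition twice per side; presentation
#' order is randomized per participant under the seed, so identical
#' parameters (including the seed) reproduce the dataset byte for byte.
#'
#' @param params A [rating_model_params()].
#' @return Long-format rating data frame (`participant`, `condition`,
#'   `side`, `repetition`, `rating`, plus `trial` giving the presentation
#'   order within participant).
#' @export
generate_ratings <- function(params = rating_model_params()) {
  stopifnot(inherits(params, "rating_model_params"))
  with_seed(params$seed, {
    design <- expand.grid(condition = rating_conditions(),
                          side = c("left", "right"),
                          repetition = 1:2,
                          stringsAsFactors = FALSE)
    out <- vector("list", params$n_participants)
    for (p in seq_len(params$n_participants)) {
      b_p <- stats::rnorm(1, 0, params$participant_sd)
      ord <- sample.int(nrow(design))
      d <- design[ord, , drop = FALSE]
      latent <- params$condition_latent_means[d$condition] + b_p +
        stats::rnorm(nrow(d), 0, params$trial_sd)
      out[[p]] <- data.frame(participant = p,
                             condition = d$condition,
                             side = d$side,
                             repetition = d$repetition,
                             rating = latent_to_rating(latent, params$cutpoints),
                             trial = seq_len(nrow(d)))
    }
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
  })
}

#' Generate a null pair dataset (equal latent means)
#'
#' Both requested conditions share one latent mean (their average under the
#' supplied parameters, plus `shift` on the second condition for power
#' studies). Used as a type-I-error / power harness for the signed-rank
#' test.
#'
#' @param params A [rating_model_params()].
#' @param conditions Length-2 character vector of distinct condition codes.
#' @param shift Latent shift added to the second condition (0 = null).
#' @return Long-format rating data frame restricted to the two conditions.
#' @export
generate_null_pair <- function(params = rating_model_params(),
                               conditions = c("A", "D"), shift = 0) {
  stopifnot(length(conditions) == 2L, conditions[1] != conditions[2],
            all(conditions %in% rating_conditions()))
  mu <- mean(params$condition_latent_means[conditions])
  p2 <- params
  p2$condition_latent_means[] <- NA_real_
  p2$condition_latent_means[conditions] <- c(mu, mu + shift)
  with_seed(params$seed, {
    design <- expand.grid(condition = conditions,
                          side = c("left", "right"),
                          repetition = 1:2,
                          stringsAsFactors = FALSE)
    out <- vector("list", params$n_participants)
    for (p in seq_len(params$n_participants)) {
      b_p <- stats::rnorm(1, 0, params$participant_sd)
      ord <- sample.int(nrow(design))
      d <- design[ord, , drop = FALSE]
      latent <- p2$condition_latent_means[d$condition] + b_p +
        stats::rnorm(nrow(d), 0, params$trial_sd)
      out[[p]] <- data.frame(participant = p,
                             condition = d$condition,
                             side = d$side,
                             repetition = d$repetition,
                             rating = latent_to_rating(latent, p2$cutpoints),
                             trial = seq_len(nrow(d)))
    }
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
  })
}

#' Rank-order recovery experiment for the rating generator
#'
#' Repeatedly generates datasets and checks whether the sample condition
#' means (from [condition_summary()]) order every pair of conditions whose
#' latent means differ in the correct direction (ties in latent means impose
#' no constraint). Reports the fraction of replicates with full recovery.
#'
#' @param params A [rating_model_params()]; its seed is the base seed.
#' @param n_reps Number of replicates (each uses seed `seed + i`).
#' @return List with `recovery_rate` and `n_reps`.
#' @export
rank_order_recovery <- function(params = rating_model_params(), n_reps = 200L) {
  mu <- params$condition_latent_means
  pairs <- utils::combn(rating_conditions(), 2)
  diffs <- mu[pairs[1, ]] - mu[pairs[2, ]]
  informative <- which(abs(diffs) > 1e-12)
  ok <- logical(n_reps)
  for (i in seq_len(n_reps)) {
    p <- params
    p$seed <- params$seed + i
    s <- condition_summary(generate_ratings(p))
    sm <- stats::setNames(s$condition_means, s$conditions)
    sdiffs <- sm[pairs[1, informative]] - sm[pairs[2, informative]]
    ok[i] <- all(sign(sdiffs) == sign(diffs[informative]))
  }
  list(recovery_rate = mean(ok), n_reps = n_reps)
}

#' Monte-Carlo rejection rate of the signed-rank test on generated data
#'
#' Generates `n_reps` paired datasets via [generate_null_pair()] (with the
#' given latent `shift`), pairs per-participant condition means, and applies
#' the exact two-sided signed-rank test at level `alpha`.
#'
#' @param params A [rating_model_params()]; its seed is the base seed.
#' @param n_reps Replicates.
#' @param alpha Significance level.
#' @param shift Latent shift of the second condition (0 = type-I error).
#' @param conditions Condition pair.
#' @return List with `rejection_rate`, `n_reps`, `alpha`.
#' @export
signed_rank_rejection_rate <- function(params = rating_model_params(),
                                       n_reps = 2000L, alpha = 0.05,
                                       shift = 0,
                                       conditions = c("A", "D")) {
  rej <- logical(n_reps)
  for (i in seq_len(n_reps)) {
    p <- params
    p$seed <- params$seed + i
    d <- generate_null_pair(p, conditions, shift)
    pp <- paired_condition_means(d, conditions[1], conditions[2])
    w <- suppressWarnings(
      wilcoxon_signed_rank(pp$mean1, pp$mean2, method = "exact"))
    rej[i] <- w$p_value < alpha
  }
  list(rejection_rate = mean(rej), n_reps = n_reps, alpha = alpha)
}
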