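#' Planted block-structured state covariances
#'
#' Builds K covariance (correlation-scale) matrices spanning the
#' segregation-integration axis with mutually distinct connectivity
#' patterns. State K is fully segregated: correlation `within_r` inside
#' each of `n_blocks` contiguous equal blocks and `between_r` between
#' blocks. State 1 is the integrated state: off-diagonals close to the
#' pair-weighted mean of the segregated pattern (with a 15 percent trace
#' of the block structure retained so the profile is not exactly
#' constant). Intermediate states carry intermediate within/between
#' amplitudes but on *interleaved* block partitions (components grouped
#' round-robin at state-specific granularity), so the planted centroids
#' differ in pattern, not merely in strength — amplitude-only
#' interpolation would make every centroid perfectly correlated with
#' every other and state identity unrecoverable by correlation. All
#' matrices are made positive definite by flooring eigenvalues at 1e-3.
#'
#' @param C number of components.
#' @param K number of states (>= 1; K = 1 returns the segregated state).
#' @param within_r within-block correlation of the segregated state.
#' @param between_r between-block correlation of the segregated state.
#' @param n_blocks number of equal blocks.
#' @return list of K symmetric positive-definite C x C matrices; attribute
#'   `blocks` carries the block assignment.
#' @export
make_block_covariances <- function(C, K, within_r = 0.6, between_r = -0.3,
                                   n_blocks = 2) {
  if (abs(within_r) >= 1 || abs(between_r) >= 1)
    stopf("correlations must lie in (-1, 1)")
  if (K < 1) stopf("K must be >= 1")
  blocks <- sort(rep(seq_len(n_blocks), length.out = C))
  pattern <- function(b) {                    # segregated pattern on partition b
    M <- ifelse(outer(b, b, "=="), within_r, between_r)
    diag(M) <- 1
    M
  }
  seg <- pattern(blocks)
  off <- upper.tri(seg)
  mean_r <- mean(seg[off])
  unif <- matrix(mean_r, C, C)
  diag(unif) <- 1
  # round-robin partition at granularity g: distinct from the contiguous
  # blocks and from other granularities
  interleaved <- function(g) {
    ((ceiling(seq_len(C) / g) - 1) %% n_blocks) + 1
  }
  # State 1 keeps a small trace (20 percent) of block structure so its
  # centroid is near-uniform but not exactly constant, which keeps
  # correlation-based state matching well defined. Intermediate states get
  # strong pattern amplitude (0.6..1): modularity is scale-invariant, so
  # the modularity axis is spanned by the uniform-admixture ratio (mainly
  # state 1 vs state K), while strong amplitudes keep every state
  # recoverable from short noisy windows.
  alphas <- if (K == 1) 1
            else if (K == 2) c(0.2, 1)
            else c(0.2, seq(0.6, 1, length.out = K - 1))
  out <- lapply(seq_len(K), function(k) {
    a <- alphas[k]
    # distinct partition per state: contiguous blocks for the segregated
    # state K, round-robin granularity 2^(k-2) for intermediates, and an
    # unused granularity for state 1's residual trace
    pat <- if (k == K) seg
           else if (k == 1) pattern(interleaved(2^(K - 2)))
           else pattern(interleaved(2^(k - 2)))
    M <- (1 - a) * unif + a * pat
    e <- eigen(M, symmetric = TRUE)
    if (any(e$values < 1e-3)) {
      M <- e$vectors %*% diag(pmax(e$values, 1e-3)) %*% t(e$vectors)
      M <- (M + t(M)) / 2
    }
    if (any(eigen(M, symmetric = TRUE, only.values = TRUE)$values <= 0))
      stopf("state covariance not positive definite after eigenvalue flooring")
    M
  })
  attr(out, "blocks") <- blocks
  out
}

#' Synthetic cohort configuration
#'
#' Defines the generative conditions: planted covariance states, a sticky
#' first-order Markov chain over states whose transition odds toward a
#' designated engaged state are boosted by the hemodynamically convolved
#' task input, AR(1)-smoothed Gaussian observations, random-walk motion
#' regressors, and behaviours linear in state dwell times.
#'
#' @param n_subjects cohort size (default 60).
#' @param n_components components C (default 20).
#' @param tr_seconds repetition time (default 2.2 s).
#' @param n_timepoints TRs per session (default 200).
#' @param n_states planted states K (default 4).
#' @param state_covariances list of K SPD matrices (default
#'   [make_block_covariances()] with the defaults above).
#' @param base_transition K x K row-stochastic matrix (default: stay
#'   probability 0.9, uniform off-diagonal).
#' @param task_coupling additive log-odds boost toward the engaged state per
#'   unit convolved stimulus amplitude; scalar (all conditions) or named
#'   per-condition vector. Default 1.
#' @param engaged_state index of the state favoured during stimulation
#'   (default 1, the integrated state).
#' @param ar_coefficient AR(1) smoothing of observations in [0, 1)
#'   (default 0.3).
#' @param motion_sd innovation SD of the motion random walks (default 0.02).
#' @param behaviour_effects per-state slopes of behaviour on mean dwell time
#'   (windows); default c(0.3, -0.3, 0.2, -0.2) recycled to K.
#' @param noise_sd behaviour noise SD (default 1).
#' @param subject_conn_sd SD of subject-level state-specific connectivity
#'   modifiers on the designated pair subset (default 0: homogeneous states).
#' @param conn_effects per-state slopes linking the connectivity modifiers to
#'   the connectivity-generated behaviour and diagnosis (default alternating
#'   +/- 1.5 recycled to K).
#' @param seed integer master seed.
#' @return validated list of class `synth_config`.
#' @export
synthetic_config <- function(n_subjects = 60, n_components = 20,
                             tr_seconds = 2.2, n_timepoints = 200,
                             n_states = 4, state_covariances = NULL,
                             base_transition = NULL, task_coupling = 1,
                             engaged_state = 1, ar_coefficient = 0.3,
                             motion_sd = 0.02, behaviour_effects = NULL,
                             noise_sd = 1, subject_conn_sd = 0,
                             conn_effects = NULL, seed = 1L) {
  K <- n_states
  if (K < 1) stopf("n_states must be >= 1")
  if (is.null(state_covariances))
    state_covariances <- make_block_covariances(n_components, K)
  if (length(state_covariances) != K)
    stopf("need %d state covariances, got %d", K, length(state_covariances))
  for (S in state_covariances) {
    if (max(abs(S - t(S))) > 1e-10) stopf("state covariance not symmetric")
    if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <= 0)
      stopf("state covariance not positive definite")
  }
  if (is.null(base_transition)) {
    stay <- 0.9
    base_transition <- matrix(if (K > 1) (1 - stay) / (K - 1) else 0, K, K)
    diag(base_transition) <- if (K > 1) stay else 1
  }
  if (any(abs(rowSums(base_transition) - 1) > 1e-10))
    stopf("transition rows must sum to 1")
  if (ar_coefficient < 0 || ar_coefficient >= 1)
    stopf("ar_coefficient must lie in [0, 1)")
  if (is.null(behaviour_effects))
    behaviour_effects <- rep(c(0.3, -0.3, 0.2, -0.2), length.out = K)
  if (is.null(conn_effects))
    conn_effects <- rep(c(1.5, -1.5), length.out = K)
  structure(list(n_subjects = n_subjects, n_components = n_components,
                 tr_seconds = tr_seconds, n_timepoints = n_timepoints,
                 n_states = K, state_covariances = state_covariances,
                 base_transition = base_transition,
                 task_coupling = task_coupling,
                 engaged_state = engaged_state,
                 ar_coefficient = ar_coefficient, motion_sd = motion_sd,
                 behaviour_effects = rep(behaviour_effects, length.out = K),
                 noise_sd = noise_sd, subject_conn_sd = subject_conn_sd,
                 conn_effects = rep(conn_effects, length.out = K),
                 blocks = attr(state_covariances, "blocks"),
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Stationary distribution of a finite Markov chain
#' @param P row-stochastic transition matrix.
#' @return stationary probability vector.
#' @export
stationary_distribution <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

# convolved stimulus amplitude on the TR grid, summed over conditions
# weighted by their coupling
task_drive <- function(cfg, design) {
  if (is.null(design) || !length(design$conditions))
    return(rep(0, cfg$n_timepoints))
  reg <- condition_regressors_tr(design, cfg$tr_seconds, cfg$n_timepoints)
  coup <- cfg$task_coupling
  if (length(coup) == 1 && is.null(names(coup)))
    coup <- setNames(rep(coup, length(design$conditions)), design$conditions)
  coup <- coup[design$conditions]
  coup[is.na(coup)] <- 0
  as.numeric(coup %*% reg)
}

#' Simulate one subject
#'
#' Draws a latent state sequence from the task-modulated Markov chain, then
#' observations y_t ~ N(0, Sigma_{s_t}) with AR(1) smoothing
#' (y_t = phi y_{t-1} + sqrt(1 - phi^2) e_t, preserving the stationary
#' covariance), plus Gaussian random-walk motion regressors.
#'
#' @param cfg a [synthetic_config()].
#' @param design a [task_design()] (or NULL for no task input).
#' @param subject_seed integer seed; identical seeds give identical output.
#' @param subject_id label for the emitted time-series.
#' @return list: `ts` (a `cts` with motion attached), `states` (latent
#'   length-T sequence), `conn_modifiers` (K-vector, zero unless
#'   `subject_conn_sd > 0`).
#' @export
simulate_subject <- function(cfg, design = NULL, subject_seed = 1L,
                             subject_id = "s01") {
  set.seed(as.integer(subject_seed))
  K <- cfg$n_states
  T_ <- cfg$n_timepoints
  C <- cfg$n_components
  drive <- task_drive(cfg, design)

  s <- sample_state_chain(cfg, drive)

  m <- rnorm(K, 0, cfg$subject_conn_sd)
  chols <- lapply(seq_len(K), function(k) {
    S <- cfg$state_covariances[[k]]
    if (m[k] != 0) {
      mask <- conn_pair_mask(cfg)
      S <- S + m[k] * mask
      ev <- eigen(S, symmetric = TRUE)
      S <- ev$vectors %*% diag(pmax(ev$values, 1e-3)) %*% t(ev$vectors)
      S <- (S + t(S)) / 2
    }
    chol(S)
  })

  Y <- matrix(0, T_, C)
  phi <- cfg$ar_coefficient
  innov_scale <- sqrt(1 - phi^2)
  prev <- as.numeric(rnorm(C) %*% chols[[s[1]]])
  Y[1, ] <- prev
  for (t in 2:T_) {
    eps <- as.numeric(rnorm(C) %*% chols[[s[t]]])
    prev <- phi * prev + innov_scale * eps
    Y[t, ] <- prev
  }

  motion <- apply(matrix(rnorm(T_ * 6, 0, cfg$motion_sd), T_, 6), 2, cumsum)
  fd <- mean(rowSums(abs(apply(motion, 2, diff))))
  list(ts = component_ts(Y, cfg$tr_seconds, subject_id = subject_id,
                         motion = motion, mean_fd = fd),
       states = s, conn_modifiers = m)
}

# draw one latent state sequence from the task-modulated chain, using the
# current RNG stream; drive is the convolved stimulus amplitude per TR
sample_state_chain <- function(cfg, drive = NULL) {
  K <- cfg$n_states
  T_ <- cfg$n_timepoints
  e <- cfg$engaged_state
  if (is.null(drive)) drive <- rep(0, T_)
  s <- integer(T_)
  pi0 <- stationary_distribution(cfg$base_transition)
  s[1] <- sample.int(K, 1, prob = pi0)
  for (t in 2:T_) {
    p <- cfg$base_transition[s[t - 1], ]
    if (drive[t] != 0) {
      logit <- log(pmax(p, 1e-12))
      logit[e] <- logit[e] + drive[t]
      p <- exp(logit - max(logit))
      p <- p / sum(p)
    }
    s[t] <- sample.int(K, 1, prob = p)
  }
  s
}

# symmetric 0/1 mask of the designated pair subset (block 1's within pairs)
conn_pair_mask <- function(cfg) {
  C <- cfg$n_components
  blocks <- cfg$blocks %||% sort(rep(1:2, length.out = C))
  mask <- matrix(0, C, C)
  in1 <- which(blocks == 1)
  mask[in1, in1] <- 1
  diag(mask) <- 0
  mask
}

#' Designated pair subset of the generator
#'
#' Indices (canonical pair order) of the component pairs carrying the
#' subject-level connectivity modifiers: the within-block-1 pairs.
#'
#' @param cfg a [synthetic_config()].
#' @return integer vector of pair indices.
#' @export
designated_pairs <- function(cfg) {
  which(fnc_vec(conn_pair_mask(cfg)) == 1)
}

#' Planted state centroids in correlation form
#' @param cfg a [synthetic_config()].
#' @return K x P matrix of vectorized planted correlation profiles.
#' @export
planted_centroids <- function(cfg) {
  t(vapply(cfg$state_covariances,
           function(S) fnc_vec(cov2cor(S)),
           numeric(pair_count(cfg$n_components))))
}

#' Dwell times and fraction times of a label sequence
#'
#' Mean maximal-run length per state (NA when a state is never visited) and
#' the fraction of samples spent in each state.
#'
#' @param s integer label sequence (values in 1..k).
#' @param k number of states.
#' @return list with `dwell` and `fraction`, each a length-k vector.
#' @export
sequence_dwell <- function(s, k) {
  r <- rle(as.integer(s))
  dwell <- vapply(seq_len(k), function(st) {
    len <- r$lengths[r$values == st]
    if (!length(len)) NA_real_ else mean(len)
  }, numeric(1))
  fraction <- vapply(seq_len(k), function(st) mean(s == st), numeric(1))
  list(dwell = dwell, fraction = fraction)
}

#' Generate behaviours from dwell times
#'
#' Each behaviour is a linear combination of per-state mean dwell times plus
#' Gaussian noise: b_i = sum_k beta_k dwell_ik + eps_i. A binary diagnosis
#' is emitted from a logistic model on state-specific mean connectivity of
#' the designated pair subset when subject-level connectivity modifiers are
#' supplied.
#'
#' @param dwell n x K matrix of per-subject mean dwell times (NAs treated
#'   as 0: a state never visited contributes nothing).
#' @param cfg a [synthetic_config()].
#' @param seed integer seed.
#' @param conn_modifiers optional n x K matrix of subject connectivity
#'   modifiers (from [simulate_subject()]).
#' @return data.frame with `behaviour` (dwell-generated), `behaviour_conn`
#'   (connectivity-generated, NA when no modifiers), `diagnosis` (0/1).
#' @export
generate_behaviour <- function(dwell, cfg, seed = 1L, conn_modifiers = NULL) {
  set.seed(as.integer(seed))
  if (any(dwell < 0, na.rm = TRUE)) stopf("dwell times must be non-negative")
  d0 <- dwell
  d0[is.na(d0)] <- 0
  n <- nrow(d0)
  b <- as.numeric(d0 %*% cfg$behaviour_effects) + rnorm(n, 0, cfg$noise_sd)
  if (!is.null(conn_modifiers)) {
    base <- vapply(cfg$state_covariances, function(S) {
      mask <- conn_pair_mask(cfg)
      mean(cov2cor(S)[mask == 1])
    }, numeric(1))
    x <- sweep(conn_modifiers, 2, base, "+")
    score <- as.numeric(x %*% cfg$conn_effects)
    b_conn <- score + rnorm(n, 0, cfg$noise_sd * 0.1)
    diag_p <- plogis(scale(score)[, 1] * 2)
    diagnosis <- rbinom(n, 1, diag_p)
  } else {
    b_conn <- rep(NA_real_, n)
    raw <- as.numeric(d0 %*% cfg$behaviour_effects)
    score <- if (sd(raw) > 0) (raw - mean(raw)) / sd(raw) else rep(0, n)
    diagnosis <- rbinom(n, 1, plogis(score))
  }
  data.frame(behaviour = b, behaviour_conn = b_conn, diagnosis = diagnosis)
}

#' Simulate a full cohort
#'
#' Runs [simulate_subject()] for every subject (seeds split from the master
#' seed), collects latent-state ground truth, and generates behaviours and
#' covariates.
#'
#' @param cfg a [synthetic_config()].
#' @param design a [task_design()] shared by all subjects, or a function
#'   `f(subject_index, seed)` returning one (event-related designs with
#'   jittered onsets).
#' @param seed master seed (default `cfg$seed`).
#' @return list: `subjects` (list of simulate_subject outputs), `truth`
#'   (centroids, state sequences, dwell/fraction matrices,
#'   behaviour-generating coefficients), `behaviour` (data.frame),
#'   `covariates` (age, sex, site, mean FD), `cfg`, `designs`.
#' @export
simulate_cohort <- function(cfg, design = NULL, seed = cfg$seed) {
  set.seed(as.integer(seed))
  n <- cfg$n_subjects
  K <- cfg$n_states
  subject_seeds <- sample.int(.Machine$integer.max - 1L, n)
  behaviour_seed <- sample.int(.Machine$integer.max - 1L, 1)
  designs <- vector("list", n)
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    di <- if (is.function(design)) design(i, subject_seeds[i]) else design
    designs[[i]] <- di
    subjects[[i]] <- simulate_subject(cfg, di, subject_seeds[i],
                                      subject_id = sprintf("s%03d", i))
  }
  dw <- t(vapply(subjects, function(s) sequence_dwell(s$states, K)$dwell,
                 numeric(K)))
  fr <- t(vapply(subjects, function(s) sequence_dwell(s$states, K)$fraction,
                 numeric(K)))
  conn <- do.call(rbind, lapply(subjects, function(s) s$conn_modifiers))
  behaviour <- generate_behaviour(dw, cfg, seed = behaviour_seed,
                                  conn_modifiers = if (cfg$subject_conn_sd > 0)
                                    conn else NULL)
  covariates <- data.frame(
    subject_id = vapply(subjects, function(s) s$ts$subject_id, character(1)),
    age = round(rnorm(n, 19, 0.8), 2),
    sex = sample(c("F", "M"), n, replace = TRUE),
    site = sample(paste0("site", 1:4), n, replace = TRUE),
    mean_fd = vapply(subjects, function(s) s$ts$mean_fd, numeric(1)))
  list(subjects = subjects,
       truth = list(centroids = planted_centroids(cfg),
                    states = lapply(subjects, `[[`, "states"),
                    dwell = dw, fraction = fr,
                    behaviour_effects = cfg$behaviour_effects,
                    conn_modifiers = conn),
       behaviour = behaviour, covariates = covariates,
       cfg = cfg, designs = designs)
}
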