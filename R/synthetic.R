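# Synthetic rater panels and evoked EEG epochs with the statistical
# structure the analysis assumes, so every pipeline stage is testable
# without recorded data.

#' Simulate a panel of semantic-differential raters
#'
#' Generates rating records around latent group-level PAD targets by the
#' exact inverse of the scoring formulas
#' (`V1 = V7 = P`, `V4 = V10 = -P`, `V5 = V11 = A`, `V2 = V8 = -A`,
#' `V3 = V9 = D`, `V6 = V12 = -D`), plus iid Gaussian rater noise on each
#' item, clipped to the `[-4, 4]` scale. With `noise_sd = 0` every record
#' scores back exactly to its target. Because scoring averages four items,
#' the per-dimension noise sd of a scored record is `noise_sd / 2`; for
#' `|target| >= 3.5` clipping attenuates recovered means toward zero.
#'
#' @param targets data.frame with columns `group` (one of `young`,
#'   `young-man`, `young-woman`, `elderly`), `stimulus_id`, `P`, `A`, `D`
#'   (each in `[-4, 4]`).
#' @param n_raters Raters per group (default 45, the reference panel size:
#'   35 students + 10 professionals). Each rater rates every stimulus of
#'   their group.
#' @param noise_sd Item-scale Gaussian noise sd (default 0.5).
#' @param seed Integer RNG seed; identical seeds give identical panels.
#' @return A validated `rating_records` data.frame.
#' @examples
#' t <- data.frame(group = "young", stimulus_id = "img1",
#'                 P = 0.8, A = 0.2, D = -0.1)
#' r <- generate_ratings(t, n_raters = 5, noise_sd = 0, seed = 1)
#' score_pad(as.numeric(r[1, paste0("v", 1:12)]))
#' @export
generate_ratings <- function(targets, n_raters = 45L, noise_sd = 0.5,
                             seed = 1L) {
  need <- c("group", "stimulus_id", "P", "A", "D")
  miss <- setdiff(need, names(targets))
  if (length(miss)) {
    stop("targets missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(n_raters >= 1L, noise_sd >= 0)
  pad <- as.matrix(targets[c("P", "A", "D")])
  if (any(abs(pad) > 4)) {
    stop("target PAD components must lie in [-4, 4]", call. = FALSE)
  }
  if (any(!targets$group %in% group_labels())) {
    stop("unknown group label in targets", call. = FALSE)
  }
  set.seed(as.integer(seed))
  out <- vector("list", 0L)
  for (g in unique(targets$group)) {
    sex <- switch(g,
                  "young-man" = rep("male", n_raters),
                  "young-woman" = rep("female", n_raters),
                  rep(c("male", "female"), length.out = n_raters))
    cohort <- group_cohort(g)
    pid <- sprintf("%s-r%02d", g, seq_len(n_raters))
    rows <- which(targets$group == g)
    for (i in rows) {
      # inverse scoring map: items whose signed sum reproduces the target
      mu <- c(pad[i, 1], -pad[i, 2], pad[i, 3], -pad[i, 1], pad[i, 2],
              -pad[i, 3], pad[i, 1], -pad[i, 2], pad[i, 3], -pad[i, 1],
              pad[i, 2], -pad[i, 3])
      items <- matrix(rnorm(n_raters * 12L, mean = rep(mu, each = n_raters),
                            sd = noise_sd), n_raters, 12L)
      items <- pmin(pmax(items, -4), 4)
      colnames(items) <- rating_item_cols()
      out[[length(out) + 1L]] <- data.frame(
        participant_id = pid, group = cohort, sex = sex,
        age_group = cohort, stimulus_id = targets$stimulus_id[i],
        items, stringsAsFactors = FALSE)
    }
  }
  as_rating_records(do.call(rbind, out))
}

#' Simulate lateralized evoked EEG epochs
#'
#' Each trial is white Gaussian background noise plus a Gaussian-shaped
#' late positive potential (LPP) on the scalp channels. The valence
#' hypothesis is embodied through multiplicative lateralization of the
#' frontal bump: for condition `like` the left frontal channels (Fp1, F3)
#' carry `(1 + lambda)` times the bump and the right counterparts
#' `(1 - lambda)`; `dislike` is mirrored; `neutral` is symmetric. Mastoid
#' channels carry noise only. In the noiseless case the frontal-asymmetry
#' index of a `like` average equals `2 * lambda * amplitude`.
#'
#' @param fs Sampling rate in Hz (default 500; the reference value is not
#'   reported, 500 Hz is a routine ERP rate).
#' @param n_trials Trials per condition (default 40, the per-image
#'   presentation count of the reference design).
#' @param channels Montage (default [default_montage()]): 8 scalp channels +
#'   2 mastoids.
#' @param noise_sd Per-sample noise sd in microvolts (default 5).
#' @param lpp_amplitude Named bump amplitude in microvolts per condition
#'   (default `c(like = 5, neutral = 3, dislike = 5)`).
#' @param lpp_latency Bump peak latency in ms (default 400; must lie inside
#'   the 250-600 ms analysis window).
#' @param lpp_width Gaussian sd of the bump in ms (default 80).
#' @param lateralization Signed fraction `lambda` in `[-1, 1]` shifting the
#'   frontal bump between hemispheres (default 0.5).
#' @param window Epoch span in ms (default -200..800).
#' @param conditions Condition labels to simulate.
#' @param seed Integer RNG seed.
#' @return An `epoch_set` with `n_trials * length(conditions)` trials.
#' @export
generate_epochs <- function(fs = 500, n_trials = 40L,
                            channels = default_montage(), noise_sd = 5,
                            lpp_amplitude = c(like = 5, neutral = 3,
                                              dislike = 5),
                            lpp_latency = 400, lpp_width = 80,
                            lateralization = 0.5, window = c(-200, 800),
                            conditions = c("like", "neutral", "dislike"),
                            seed = 1L) {
  stopifnot(n_trials >= 1L, noise_sd >= 0, lpp_width > 0,
            abs(lateralization) <= 1)
  if (lpp_latency < 250 || lpp_latency > 600) {
    stop("lpp_latency must lie within the 250-600 ms analysis window",
         call. = FALSE)
  }
  if (lpp_latency <= window[1] || lpp_latency >= window[2]) {
    stop("lpp_latency outside the epoch span", call. = FALSE)
  }
  amp_of <- function(cond) {
    if (!cond %in% names(lpp_amplitude)) {
      stop("no lpp_amplitude given for condition '", cond, "'",
           call. = FALSE)
    }
    lpp_amplitude[[cond]]
  }
  set.seed(as.integer(seed))
  n_pre <- round(fs * -window[1] / 1000)
  n_post <- round(fs * window[2] / 1000)
  ns <- n_pre + n_post
  tt <- window[1] + (seq_len(ns) - 1L) * 1000 / fs
  bump <- exp(-(tt - lpp_latency)^2 / (2 * lpp_width^2))
  scalp <- setdiff(channels, mastoid_channels())
  left <- c("Fp1", "F3"); right <- c("Fp2", "F4")
  n_all <- n_trials * length(conditions)
  data <- array(rnorm(n_all * length(channels) * ns, sd = noise_sd),
                c(n_all, length(channels), ns))
  condition <- rep(conditions, each = n_trials)
  for (tr in seq_len(n_all)) {
    lam <- switch(condition[tr], like = lateralization,
                  dislike = -lateralization, 0)
    a <- amp_of(condition[tr])
    for (ch in scalp) {
      f <- if (ch %in% left) 1 + lam else if (ch %in% right) 1 - lam else 1
      ci <- match(ch, channels)
      data[tr, ci, ] <- data[tr, ci, ] + a * f * bump
    }
  }
  epoch_set(data, fs = fs, t0 = window[1], channels = channels,
            condition = condition)
}
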