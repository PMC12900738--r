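# Core PAD arithmetic: item scoring, octant typing, normative proximity,
# nearest-emotion preference, SMD effect size, pleasure bands, aggregation.

#' Normative PAD profiles of eight emotions
#'
#' Reference points in Pleasure-Arousal-Dominance space for eight named
#' emotions, from the standardized Chinese PAD instrument. Row order is the
#' canonical inventory order and is the tie-break order used by
#' [nearest_emotion()].
#'
#' @return A data.frame with columns `label`, `PN`, `AN`, `DN` (8 rows).
#' @examples
#' pad_norms()
#' @export
pad_norms <- function() {
  data.frame(
    label = c("Joyful", "Relaxed", "Surprise", "Dependent",
              "Boring", "Fear", "Contempt", "Disgust"),
    PN = c(2.77, 2.19, 1.72, 0.39, -0.53, -0.95, -1.58, -1.80),
    AN = c(1.21, -0.66, 1.71, -0.81, -1.25, 0.32, 0.32, 0.40),
    DN = c(1.42, 1.05, 0.22, -1.48, -0.84, -0.63, 1.02, 0.67),
    stringsAsFactors = FALSE
  )
}

#' Sign-octant emotion categories
#'
#' The eight emotion categories defined by the sign pattern of (P, A, D).
#' This vocabulary (which contains Mild and Anxiety) is distinct from the
#' normative-profile vocabulary of [pad_norms()] (which contains Surprise and
#' Fear); no cross-mapping between the two is defined.
#'
#' @return A data.frame with columns `label`, `sP`, `sA`, `sD`, where the
#'   sign columns are `+1` or `-1`.
#' @export
pad_octants <- function() {
  data.frame(
    label = c("Joyful", "Dependent", "Relaxed", "Mild",
              "Boring", "Contempt", "Anxiety", "Disgust"),
    sP = c(1, 1, 1, 1, -1, -1, -1, -1),
    sA = c(1, 1, -1, -1, -1, -1, 1, 1),
    sD = c(1, -1, 1, -1, -1, 1, -1, 1),
    stringsAsFactors = FALSE
  )
}

validate_items <- function(items, where = "items") {
  if (!is.numeric(items) || length(items) != 12L) {
    stop(where, ": expected exactly 12 numeric item scores, got ",
         length(items), call. = FALSE)
  }
  if (anyNA(items)) {
    stop(where, ": missing value at item index ",
         paste(which(is.na(items)), collapse = ", "),
         "; missing items are rejected, not imputed", call. = FALSE)
  }
  bad <- which(items < -4 | items > 4)
  if (length(bad)) {
    stop(where, ": item V", bad[1], " = ", items[bad[1]],
         " outside the [-4, 4] scale", call. = FALSE)
  }
  invisible(items)
}

#' Score a 12-item PAD semantic-differential response
#'
#' Converts the twelve bipolar item scores (9-point scale, -4..+4) of one
#' response into the three PAD dimensions:
#' \deqn{P = (V_1 - V_4 + V_7 - V_{10})/4}
#' \deqn{A = (-V_2 + V_5 - V_8 + V_{11})/4}
#' \deqn{D = (V_3 - V_6 + V_9 - V_{12})/4}
#'
#' @param items Numeric vector of length 12, each in `[-4, 4]`.
#' @return Named numeric vector `c(P=, A=, D=)`, each in `[-4, 4]`.
#' @examples
#' score_pad(c(4, 0, 0, -4, 0, 0, 4, 0, 0, -4, 0, 0))  # maximal pleasure
#' @export
score_pad <- function(items) {
  validate_items(items)
  c(P = (items[1] - items[4] + items[7] - items[10]) / 4,
    A = (-items[2] + items[5] - items[8] + items[11]) / 4,
    D = (items[3] - items[6] + items[9] - items[12]) / 4)
}

# vectorized scoring: m is an n x 12 matrix -> n x 3 matrix
score_pad_matrix <- function(m) {
  stopifnot(is.matrix(m), ncol(m) == 12L)
  cbind(P = (m[, 1] - m[, 4] + m[, 7] - m[, 10]) / 4,
        A = (-m[, 2] + m[, 5] - m[, 8] + m[, 11]) / 4,
        D = (m[, 3] - m[, 6] + m[, 9] - m[, 12]) / 4)
}

as_pad <- function(pad) {
  if (is.list(pad) && all(c("P", "A", "D") %in% names(pad))) {
    pad <- c(P = pad$P, A = pad$A, D = pad$D)
  }
  pad <- as.numeric(pad)
  if (length(pad) != 3L || anyNA(pad) || any(!is.finite(pad))) {
    stop("a PAD vector must be 3 finite numbers (P, A, D)", call. = FALSE)
  }
  names(pad) <- c("P", "A", "D")
  pad
}

#' Classify a PAD vector into its sign octant
#'
#' Maps the sign triple of (P, A, D) to one of the eight octant emotion
#' categories of [pad_octants()]. An exactly-zero component has no sign;
#' under the default policy it is counted as negative and `zero_flag` is set.
#'
#' @param pad Numeric length-3 PAD vector (P, A, D).
#' @param zero_policy `"negative"` (default) or `"positive"`: the sign
#'   assigned to an exactly-zero component.
#' @return List with `label`, `signs` (named `+1`/`-1` triple) and
#'   `zero_flag`.
#' @examples
#' classify_octant(c(0.8, 0.21, -0.06))$label  # "Dependent"
#' @export
classify_octant <- function(pad, zero_policy = c("negative", "positive")) {
  pad <- as_pad(pad)
  zero_policy <- match.arg(zero_policy)
  zero_sign <- if (zero_policy == "negative") -1 else 1
  s <- sign(pad)
  zero_flag <- any(s == 0)
  s[s == 0] <- zero_sign
  oct <- pad_octants()
  hit <- oct$sP == s[1] & oct$sA == s[2] & oct$sD == s[3]
  list(label = oct$label[hit], signs = setNames(s, c("P", "A", "D")),
       zero_flag = zero_flag)
}

as_norm_point <- function(norm, norms = pad_norms()) {
  if (is.character(norm) && length(norm) == 1L) {
    i <- match(norm, norms$label)
    if (is.na(i)) stop("unknown emotion norm label: ", norm, call. = FALSE)
    return(c(norms$PN[i], norms$AN[i], norms$DN[i]))
  }
  if (is.data.frame(norm)) {
    stopifnot(nrow(norm) == 1L)
    return(c(norm$PN, norm$AN, norm$DN))
  }
  as_pad(norm)
}

#' Euclidean proximity between a PAD vector and a normative emotion
#'
#' The proximity (distance) between a measured PAD triple and a normative
#' emotion point:
#' \deqn{L_i = \sqrt{(P-P_N)^2 + (A-A_N)^2 + (D-D_N)^2}}
#' The smaller the proximity, the closer the measured emotional state is to
#' the named emotion.
#'
#' @param pad Numeric length-3 PAD vector.
#' @param norm A norm label (looked up in `norms`), a one-row data.frame with
#'   `PN`, `AN`, `DN`, or a numeric length-3 point.
#' @param norms Norm inventory used for label lookup, default [pad_norms()].
#' @return Non-negative numeric scalar.
#' @examples
#' proximity(c(0.1963, 0.0786, -0.0333), "Surprise")  # 2.2466
#' @export
proximity <- function(pad, norm, norms = pad_norms()) {
  pad <- as_pad(pad)
  pt <- as_norm_point(norm, norms)
  sqrt(sum((pad - pt)^2))
}

#' Proximity profile against a full norm inventory
#'
#' @param pad Numeric length-3 PAD vector.
#' @param norms Norm table (as [pad_norms()]).
#' @return Named numeric vector of distances, one per norm, in table order.
#' @export
proximity_profile <- function(pad, norms = pad_norms()) {
  pad <- as_pad(pad)
  d <- sqrt((pad[1] - norms$PN)^2 + (pad[2] - norms$AN)^2 +
              (pad[3] - norms$DN)^2)
  setNames(d, norms$label)
}

#' Nearest normative emotion (emotional preference)
#'
#' The emotional preference of a measured PAD state is the normative emotion
#' with the minimum proximity. Exact ties are broken by norm-table order and
#' flagged.
#'
#' @inheritParams proximity_profile
#' @return List with `label`, `distance`, `tie_flag`.
#' @examples
#' nearest_emotion(c(-0.4595, 0.2667, 0.1214))  # Fear, 0.8989
#' @export
nearest_emotion <- function(pad, norms = pad_norms()) {
  if (!is.data.frame(norms) || nrow(norms) == 0L) {
    stop("norm inventory must be a non-empty data.frame", call. = FALSE)
  }
  if (anyDuplicated(norms$label)) {
    stop("norm labels must be unique", call. = FALSE)
  }
  d <- proximity_profile(pad, norms)
  i <- which.min(d)  # first minimum = earliest in table order
  list(label = names(d)[i], distance = unname(d[i]),
       tie_flag = sum(d == d[i]) > 1L)
}

#' Variance-free standardized mean difference
#'
#' Effect-size measure for descriptive comparisons of two mean emotional
#' responses when no variance estimates are available:
#' \deqn{SMD = (M_1 - M_2) / (|M_1| + |M_2|)}
#' Bounded in `[-1, 1]`; `|SMD| = 1` exactly when the two means have opposite
#' signs (or one is zero), conventionally read as a large effect.
#'
#' @param m1,m2 The two means being compared; not both zero.
#' @return Numeric scalar in `[-1, 1]`.
#' @examples
#' smd(0.8, -0.25)  # 1
#' @export
smd <- function(m1, m2) {
  stopifnot(is.numeric(m1), is.numeric(m2), length(m1) == 1L,
            length(m2) == 1L, is.finite(m1), is.finite(m2))
  if (m1 == 0 && m2 == 0) {
    stop("SMD undefined for m1 = m2 = 0 (zero denominator)", call. = FALSE)
  }
  (m1 - m2) / (abs(m1) + abs(m2))
}

band_nodes <- function(scheme) {
  switch(scheme,
         painting = c(-1.25, -0.25, 0.25, 1.25),
         interior = c(-1.50, -0.20, 0.50, 1.50))
}

#' Classify a pleasure value into a preference band
#'
#' Pleasure means are classified into Unpleased / General / Pleased bands
#' between four scheme-specific nodes (painting: -1.25, -0.25, 0.25, 1.25;
#' interior: -1.5, -0.2, 0.5, 1.5). Interior band nodes touch, so a value
#' exactly on a shared node is assigned to the band farther from zero. Values
#' outside the outer nodes are flagged and assigned to the nearest band.
#'
#' @param p Pleasure value (numeric scalar).
#' @param scheme `"painting"` or `"interior"`.
#' @return List with `band` (one of `"Unpleased"`, `"General"`, `"Pleased"`)
#'   and `out_of_range` (logical).
#' @examples
#' classify_pleasure_band(-0.25, "painting")$band  # "Unpleased" (shared node)
#' @export
classify_pleasure_band <- function(p, scheme = c("painting", "interior")) {
  scheme <- match.arg(scheme)
  stopifnot(is.numeric(p), length(p) == 1L, is.finite(p))
  n <- band_nodes(scheme)
  out <- p < n[1] || p > n[4]
  band <- if (p <= n[2]) "Unpleased" else if (p < n[3]) "General" else "Pleased"
  list(band = band, out_of_range = out)
}

## ---- rating records ---------------------------------------------------

rating_item_cols <- function() paste0("v", 1:12)

group_labels <- function() c("young", "young-man", "young-woman", "elderly")

# cohort ("young"/"elderly") of a group label
group_cohort <- function(group) {
  ifelse(group %in% c("young", "young-man", "young-woman"), "young", group)
}

#' Validate a table of rating records
#'
#' Checks that a data.frame of semantic-differential responses has the
#' required columns (`participant_id`, `group`, `sex`, `stimulus_id`,
#' `v1`..`v12`), that every item is numeric, non-missing and within the
#' `[-4, 4]` scale, and that group labels are known. Errors name the
#' offending row and field.
#'
#' @param records data.frame of ratings, one response per row.
#' @return The validated data.frame (invisibly classed `rating_records`).
#' @export
as_rating_records <- function(records) {
  need <- c("participant_id", "group", "sex", "stimulus_id",
            rating_item_cols())
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("ratings table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  badg <- which(!records$group %in% c(group_labels()))
  if (length(badg)) {
    stop("row ", badg[1], ": unknown group label '", records$group[badg[1]],
         "'", call. = FALSE)
  }
  bads <- which(!records$sex %in% c("male", "female"))
  if (length(bads)) {
    stop("row ", bads[1], ": sex must be 'male' or 'female', got '",
         records$sex[bads[1]], "'", call. = FALSE)
  }
  for (cn in rating_item_cols()) {
    v <- records[[cn]]
    if (!is.numeric(v)) {
      stop("column ", cn, " is not numeric", call. = FALSE)
    }
    if (anyNA(v)) {
      stop("row ", which(is.na(v))[1], ", field ", cn,
           ": missing item score (missing values are rejected, not imputed)",
           call. = FALSE)
    }
    bad <- which(v < -4 | v > 4)
    if (length(bad)) {
      stop("row ", bad[1], ", field ", cn, ": value ", v[bad[1]],
           " outside the [-4, 4] scale", call. = FALSE)
    }
  }
  class(records) <- unique(c("rating_records", class(records)))
  records
}

# logical membership of each record in a (possibly nested) group
records_in_group <- function(records, group) {
  cohort <- group_cohort(records$group)
  switch(group,
         "young" = cohort == "young",
         "elderly" = cohort == "elderly",
         "young-man" = cohort == "young" & records$sex == "male",
         "young-woman" = cohort == "young" & records$sex == "female",
         stop("unknown group label: ", group, call. = FALSE))
}

#' Group-level mean PAD per stimulus
#'
#' Scores every record and averages the per-record PAD vectors within each
#' requested group x stimulus cell (each participant contributes one response
#' per stimulus). If `stimulus_map` maps stimulus ids to style labels, images
#' of the same style can be collapsed either participant-first (average a
#' participant's images, then participants; default) or pooled over all
#' records.
#'
#' @param records Validated rating records (see [as_rating_records()]).
#' @param groups Group labels to aggregate; defaults to all four.
#' @param stimulus_map Optional named character vector mapping
#'   `stimulus_id` to a collapsed label (e.g. image -> style).
#' @param participant_first When collapsing via `stimulus_map`, average
#'   within participant across images first (default `TRUE`).
#' @return data.frame with columns `group`, `stimulus_id`, `n` (number of
#'   participants), `P`, `A`, `D`. Empty cells are absent (missing), never
#'   reported as zero.
#' @export
aggregate_group <- function(records, groups = group_labels(),
                            stimulus_map = NULL, participant_first = TRUE) {
  records <- as_rating_records(as.data.frame(records))
  pads <- score_pad_matrix(as.matrix(records[rating_item_cols()]))
  stim <- as.character(records$stimulus_id)
  if (!is.null(stimulus_map)) {
    unknown <- setdiff(unique(stim), names(stimulus_map))
    if (length(unknown)) {
      stop("stimulus_map has no entry for: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    stim <- unname(stimulus_map[stim])
  }
  out <- list()
  for (g in groups) {
    keep <- records_in_group(records, g)
    if (!any(keep)) next
    df <- data.frame(pid = records$participant_id[keep], stim = stim[keep],
                     pads[keep, , drop = FALSE], stringsAsFactors = FALSE)
    if (!is.null(stimulus_map) && participant_first) {
      # one value per participant x collapsed stimulus, then across participants
      df <- stats::aggregate(cbind(P, A, D) ~ pid + stim, df, mean)
    }
    agg <- stats::aggregate(cbind(P, A, D) ~ stim, df, mean)
    n <- stats::aggregate(pid ~ stim, df,
                          function(x) length(unique(x)))
    out[[g]] <- data.frame(group = g, stimulus_id = agg$stim,
                           n = n$pid[match(agg$stim, n$stim)],
                           P = agg$P, A = agg$A, D = agg$D,
                           stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(group = character(), stimulus_id = character(),
                      n = integer(), P = numeric(), A = numeric(),
                      D = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Preference results from pre-scored PAD means
#'
#' Runs the typing/preference stage on a table of PAD means (one row per
#' group x stimulus): sign-octant category, proximity to every normative
#' emotion, nearest emotion, and pleasure band.
#'
#' @param pad_table data.frame with columns `group`, `stimulus_id`, `P`,
#'   `A`, `D` (an `n` column is carried through if present).
#' @param norms Norm inventory, default [pad_norms()].
#' @param scheme Pleasure-band scheme, `"painting"` or `"interior"`.
#' @param zero_policy Sign policy for exactly-zero components, see
#'   [classify_octant()].
#' @return data.frame of class `preference_result`: one row per input row
#'   with octant label, `prox_<emotion>` columns, `nearest_emotion`,
#'   `nearest_distance`, `tie_flag`, `pleasure_band`, `band_out_of_range`.
#' @export
preference_from_pad <- function(pad_table, norms = pad_norms(),
                                scheme = c("painting", "interior"),
                                zero_policy = c("negative", "positive")) {
  scheme <- match.arg(scheme)
  zero_policy <- match.arg(zero_policy)
  need <- c("group", "stimulus_id", "P", "A", "D")
  miss <- setdiff(need, names(pad_table))
  if (length(miss)) {
    stop("pad_table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(pad_table)
  prox <- matrix(NA_real_, n, nrow(norms),
                 dimnames = list(NULL, paste0("prox_", norms$label)))
  octant <- character(n); zero_flag <- logical(n)
  near <- character(n); near_d <- numeric(n); tie <- logical(n)
  band <- character(n); oor <- logical(n)
  for (i in seq_len(n)) {
    pad <- c(pad_table$P[i], pad_table$A[i], pad_table$D[i])
    oc <- classify_octant(pad, zero_policy)
    octant[i] <- oc$label; zero_flag[i] <- oc$zero_flag
    prox[i, ] <- proximity_profile(pad, norms)
    ne <- nearest_emotion(pad, norms)
    near[i] <- ne$label; near_d[i] <- ne$distance; tie[i] <- ne$tie_flag
    bd <- classify_pleasure_band(pad_table$P[i], scheme)
    band[i] <- bd$band; oor[i] <- bd$out_of_range
  }
  res <- data.frame(group = pad_table$group,
                    stimulus_id = pad_table$stimulus_id,
                    n = if ("n" %in% names(pad_table)) pad_table$n
                        else rep(NA_integer_, n),
                    P = pad_table$P, A = pad_table$A, D = pad_table$D,
                    octant = octant, zero_flag = zero_flag,
                    stringsAsFactors = FALSE)
  res <- cbind(res, as.data.frame(prox))
  res$nearest_emotion <- near
  res$nearest_distance <- near_d
  res$tie_flag <- tie
  res$pleasure_band <- band
  res$band_out_of_range <- oor
  class(res) <- c("preference_result", class(res))
  res
}

#' Full PAD preference pipeline
#'
#' Scores raw rating records, aggregates group x stimulus PAD means, and
#' derives the preference profile (octant, normative proximities, nearest
#' emotion, pleasure band) for every cell. Deterministic given its inputs.
#'
#' @inheritParams aggregate_group
#' @inheritParams preference_from_pad
#' @return A `preference_result` data.frame, one row per group x stimulus.
#' @examples
#' recs <- generate_ratings(
#'   data.frame(group = "young", stimulus_id = "s1", P = 1, A = 0.5, D = 0.2),
#'   n_raters = 8, noise_sd = 0.3, seed = 42)
#' run_pad_pipeline(recs, groups = "young")
#' @export
run_pad_pipeline <- function(records, norms = pad_norms(),
                             scheme = c("painting", "interior"),
                             groups = group_labels(), stimulus_map = NULL,
                             participant_first = TRUE,
                             zero_policy = c("negative", "positive")) {
  agg <- aggregate_group(records, groups = groups,
                         stimulus_map = stimulus_map,
                         participant_first = participant_first)
  if (nrow(agg) == 0L) {
    res <- preference_from_pad(
      data.frame(group = character(), stimulus_id = character(),
                 P = numeric(), A = numeric(), D = numeric()),
      norms = norms, scheme = scheme, zero_policy = zero_policy)
    return(res)
  }
  preference_from_pad(agg, norms = norms, scheme = scheme,
                      zero_policy = zero_policy)
}
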