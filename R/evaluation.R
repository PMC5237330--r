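#' Overlap and distance measures between binary shapes
#'
#' `dice(A,B) = 2 V(A&B) / (V(A) + V(B))`,
#' `jaccard(A,B) = V(A&B) / V(A|B)` (so `jaccard <= dice` and
#' `jaccard = dice / (2 - dice)`), and the Hausdorff distance
#' `max(sup_{x in A} inf_{y in B} d(x,y), sup_{y in B} inf_{x in A} d(x,y))`
#' over the shapes' voxel centres, spacing-aware, in mm.
#'
#' @param A,B [binary_volume()]s on a common frame; both-empty pairs (Dice,
#'   Jaccard) and any empty shape (Hausdorff) are undefined and raise an
#'   error.
#' @return A scalar: Dice/Jaccard in `[0,1]`, Hausdorff in mm `>= 0`.
#' @export
dice <- function(A, B) {
  assert_common_frame(list(A, B))
  va <- sum(A$data); vb <- sum(B$data)
  if (va + vb == 0L)
    stop("Dice undefined: both shapes are empty", call. = FALSE)
  2 * sum(A$data & B$data) / (va + vb)
}

#' @rdname dice
#' @export
jaccard <- function(A, B) {
  assert_common_frame(list(A, B))
  un <- sum(A$data | B$data)
  if (un == 0L)
    stop("Jaccard undefined: both shapes are empty", call. = FALSE)
  sum(A$data & B$data) / un
}

#' @rdname dice
#' @export
hausdorff <- function(A, B) {
  assert_common_frame(list(A, B))
  if (sum(A$data) == 0L || sum(B$data) == 0L)
    stop("Hausdorff undefined for an empty shape", call. = FALSE)
  g <- A$grid
  dB <- distance_to_set(B$data, g$dims, g$spacing)
  dA <- distance_to_set(A$data, g$dims, g$spacing)
  max(max(dB[A$data == 1L]), max(dA[B$data == 1L]))
}

#' Mean-probability measure of a probabilistic atlas (IProb)
#'
#' `IProb(P, S) = mean of P inside S - mean of P outside S`, the integrals
#' taken as spacing-weighted voxel sums over the common window `W` (the full
#' grid). The first term is a sensibility, the complement of the second a
#' specificity; the measure lives in `[-1, 1]` and equals 1 exactly when
#' `P` is the indicator of `S`.
#'
#' @param P a [probability_volume()].
#' @param S a [binary_volume()] with `0 < V(S) < V(W)`.
#' @return Scalar in `[-1, 1]`.
#' @export
iprob <- function(P, S) {
  assert_common_frame(list(P, S))
  ns <- sum(S$data)
  if (ns == 0L || ns == length(S$data))
    stop("IProb undefined: S must be neither empty nor the whole window",
         call. = FALSE)
  inside <- S$data == 1L
  mean(P$data[inside]) - mean(P$data[!inside])
}

#' Best-threshold evaluation of a probabilistic atlas
#'
#' Sweeps thresholds over the atlas (default `0, 0.1, ..., 0.9`), converts
#' each into a binary shape ([threshold_atlas()], strict inequality) and
#' reports, per measure, the best value achieved against the truth (max for
#' Dice/Jaccard, min for Hausdorff) together with the threshold that
#' produced it (lowest threshold on ties). Thresholds yielding an empty
#' shape are skipped where the measure is undefined.
#'
#' @param P a [probability_volume()].
#' @param truth a non-empty [binary_volume()].
#' @param thresholds thresholds in `[0, 1)`.
#' @return A data frame with columns `measure`, `value`, `threshold`.
#' @export
best_threshold_eval <- function(P, truth, thresholds = seq(0, 0.9, by = 0.1)) {
  assert_common_frame(list(P, truth))
  rows <- list()
  per_t <- lapply(thresholds, function(t) {
    bin <- threshold_atlas(P, t)
    empty <- sum(bin$data) == 0L
    list(t = t,
         dice = if (!empty) dice(bin, truth) else NA_real_,
         jaccard = if (!empty) jaccard(bin, truth) else NA_real_,
         hausdorff = if (!empty) hausdorff(bin, truth) else NA_real_)
  })
  pick <- function(measure, maximize) {
    vals <- vapply(per_t, function(x) x[[measure]], 0)
    if (all(is.na(vals)))
      stop("all thresholds degenerate: ", measure, " undefined",
           call. = FALSE)
    best <- if (maximize) which(vals == max(vals, na.rm = TRUE))
            else which(vals == min(vals, na.rm = TRUE))
    i <- best[1] # lowest threshold on ties
    data.frame(measure = measure, value = vals[i],
               threshold = thresholds[i])
  }
  out <- rbind(pick("dice", TRUE), pick("jaccard", TRUE),
               pick("hausdorff", FALSE))
  rownames(out) <- NULL
  out
}

#' Leave-one-out atlas evaluation
#'
#' The evaluation harness: the whole sample is coregistered once under the
#' chosen registration model (reference selected automatically unless
#' given); then, for each exploration, an atlas is built from the aligned
#' explorations of all *other* patients and compared with the held-out
#' exploration's aligned ground truth. Probabilistic atlases (NCF, GLM) are
#' scored by [best_threshold_eval()] for the binary measures plus [iprob()];
#' the statistical atlas (STA) is binary, scored directly, and carries no
#' IProb and no threshold.
#'
#' @param sample list of [binary_volume()]s (one per exploration) on a
#'   common frame.
#' @param patient_ids vector (length of `sample`) assigning each exploration
#'   to a patient; explorations of the held-out patient never enter the
#'   atlas.
#' @param atlas_method `"NCF"`, `"GLM"` or `"STA"`.
#' @param reg_model `"rigid"`, `"similarity"`, `"affine"` or `"demons"`.
#' @param reference `"auto"` or a reference index, see [coregister_sample()].
#' @param opts registration settings, see [reg_opts()].
#' @param cfg GLM settings, see [glm_config()]; ignored otherwise.
#' @param sta_args list of arguments for [statistical_atlas()].
#' @return A data frame of evaluation records: `case_id`, `patient`,
#'   `method`, `dice`, `jaccard`, `hausdorff` (mm), `iprob`,
#'   `threshold_dice/jaccard/hausdorff` (NA for STA).
#' @export
leave_one_out <- function(sample, patient_ids,
                          atlas_method = c("NCF", "GLM", "STA"),
                          reg_model = c("rigid", "similarity", "affine",
                                        "demons"),
                          reference = "auto", opts = reg_opts(),
                          cfg = glm_config(), sta_args = list()) {
  atlas_method <- match.arg(atlas_method)
  reg_model <- match.arg(reg_model)
  stopifnot(length(patient_ids) == length(sample))
  if (length(unique(patient_ids)) < 3L)
    stop("need >= 3 patients for leave-one-out", call. = FALSE)
  co <- coregister_sample(sample, reg_model, reference, opts)
  aligned <- co$aligned
  method <- paste0(atlas_method, "-", method_letter(reg_model))
  rows <- lapply(seq_along(aligned), function(e) {
    train <- aligned[patient_ids != patient_ids[e]]
    truth <- aligned[[e]]
    if (atlas_method == "STA") {
      sta <- do.call(statistical_atlas, c(list(train), sta_args))
      data.frame(case_id = e, patient = patient_ids[e], method = method,
                 dice = dice(sta$atlas, truth),
                 jaccard = jaccard(sta$atlas, truth),
                 hausdorff = hausdorff(sta$atlas, truth),
                 iprob = NA_real_, threshold_dice = NA_real_,
                 threshold_jaccard = NA_real_,
                 threshold_hausdorff = NA_real_)
    } else {
      P <- if (atlas_method == "NCF") ncf_atlas(train)
           else glm_atlas(train, cfg)
      bt <- best_threshold_eval(P, truth)
      data.frame(case_id = e, patient = patient_ids[e], method = method,
                 dice = bt$value[bt$measure == "dice"],
                 jaccard = bt$value[bt$measure == "jaccard"],
                 hausdorff = bt$value[bt$measure == "hausdorff"],
                 iprob = iprob(P, truth),
                 threshold_dice = bt$threshold[bt$measure == "dice"],
                 threshold_jaccard = bt$threshold[bt$measure == "jaccard"],
                 threshold_hausdorff = bt$threshold[bt$measure == "hausdorff"])
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

method_letter <- function(reg_model) {
  switch(reg_model, rigid = "R", similarity = "TRS", affine = "A",
         demons = "D")
}

#' Compare evaluation records across methods
#'
#' Summarizes per-method mean and standard deviation of each measure and
#' runs all unordered pairwise comparisons with paired two-sided t tests on
#' the per-case values (the same held-out cases are scored under every
#' method). P values are multiplicity-adjusted per measure (Holm by
#' default); a pair is flagged significant below `alpha` and the winner
#' (higher Dice/Jaccard/IProb, lower Hausdorff) recorded.
#'
#' @param records data frame as returned by (rows of several)
#'   [leave_one_out()] runs; must contain `case_id`, `method` and the
#'   measure columns.
#' @param adjust `"holm"`, `"bonferroni"` or `"none"`.
#' @param alpha significance level for the adjusted p values.
#' @return A list with `summary` (method x measure mean/sd), `tests` (one
#'   row per method pair and measure: statistic, p, p_adjusted, significant,
#'   winner), `n_methods`, `n_pairs`.
#' @export
compare_methods <- function(records, adjust = c("holm", "bonferroni", "none"),
                            alpha = 0.05) {
  adjust <- match.arg(adjust)
  stopifnot(all(c("case_id", "method") %in% names(records)))
  measures <- intersect(c("dice", "jaccard", "hausdorff", "iprob"),
                        names(records))
  methods <- unique(records$method)
  n_m <- length(methods)
  if (n_m < 2L) stop("need >= 2 methods to compare", call. = FALSE)
  summary <- do.call(rbind, lapply(methods, function(m) {
    sub <- records[records$method == m, ]
    do.call(rbind, lapply(measures, function(ms) {
      v <- sub[[ms]]
      data.frame(method = m, measure = ms,
                 mean = mean(v), sd = stats::sd(v), n = sum(!is.na(v)))
    }))
  }))
  pairs <- utils::combn(methods, 2, simplify = FALSE)
  tests <- do.call(rbind, lapply(measures, function(ms) {
    do.call(rbind, lapply(pairs, function(pr) {
      a <- records[records$method == pr[1], ]
      b <- records[records$method == pr[2], ]
      common <- intersect(a$case_id, b$case_id)
      if (length(common) < 2L)
        stop("unpaired case sets for methods ", pr[1], " vs ", pr[2],
             call. = FALSE)
      va <- a[[ms]][match(common, a$case_id)]
      vb <- b[[ms]][match(common, b$case_id)]
      keep <- !is.na(va) & !is.na(vb)
      va <- va[keep]; vb <- vb[keep]
      if (length(va) < 2L || all(abs(va - vb) < 1e-15)) {
        stat <- 0; p <- 1
      } else {
        tt <- stats::t.test(va, vb, paired = TRUE)
        stat <- unname(tt$statistic); p <- tt$p.value
      }
      higher_better <- ms != "hausdorff"
      winner <- if (mean(va) == mean(vb)) NA_character_
                else if ((mean(va) > mean(vb)) == higher_better) pr[1]
                else pr[2]
      data.frame(measure = ms, method_a = pr[1], method_b = pr[2],
                 mean_a = mean(va), mean_b = mean(vb),
                 statistic = stat, p = p, winner = winner)
    }))
  }))
  tests$p_adjusted <- NA_real_
  for (ms in measures) {
    sel <- tests$measure == ms
    tests$p_adjusted[sel] <- stats::p.adjust(tests$p[sel], method = adjust)
  }
  tests$significant <- tests$p_adjusted < alpha
  tests$winner[!tests$significant] <- NA_character_
  rownames(tests) <- NULL
  list(summary = summary, tests = tests, n_methods = n_m,
       n_pairs = length(pairs))
}
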