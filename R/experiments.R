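# Study harnesses: the ISD reproducibility study (virtual observer, repeated
# segmentation at ISD 1/2/3 mm) and the patient-based vs time-based data
# partition study for the segmentation network.

#' Partition a baseline/follow-up cohort for network training
#'
#' Patient-based: half the patients contribute both their baseline and
#' follow-up volumes to training; the other half's baselines form the
#' validation set and their follow-ups the test set. Time-based: all
#' baseline volumes train; the follow-up volumes are split between
#' validation and test. With the same cohort and seed the test set is
#' identical under both schemes.
#'
#' @param cohort list of patient pairs from [sample_cohort()].
#' @param scheme `"patient_based"` or `"time_based"`.
#' @param seed seed of the patient shuffle.
#' @return object of class `partition_plan` with data frames `train`,
#'   `validation`, `test` (`patient_id`, `timepoint`).
#' @export
make_partition <- function(cohort, scheme = c("patient_based", "time_based"),
                           seed = 1) {
  scheme <- match.arg(scheme)
  n <- length(cohort)
  if (n < 2L) stop("partitioning needs at least 2 patients")
  for (p in cohort)
    if (is.null(p$baseline) || is.null(p$followup))
      stop("every patient needs both timepoints")
  ids <- vapply(cohort, function(p) p$baseline$patient_id, 1L)
  perm <- with_seed(seed, sample(n))
  half_a <- sort(ids[perm[seq_len(ceiling(n / 2))]]) # training half
  half_b <- sort(setdiff(ids, half_a))               # held-out half
  df <- function(id, tp) data.frame(patient_id = id, timepoint = tp)
  plan <- if (scheme == "patient_based") {
    list(train = rbind(df(half_a, "baseline"), df(half_a, "followup")),
         validation = df(half_b, "baseline"),
         test = df(half_b, "followup"))
  } else {
    list(train = df(sort(ids), "baseline"),
         validation = df(half_a, "followup"),
         test = df(half_b, "followup"))
  }
  structure(c(plan, list(scheme = scheme, seed = seed)),
            class = "partition_plan")
}

#' @export
print.partition_plan <- function(x, ...) {
  cat(sprintf("<partition_plan> %s: %d train / %d validation / %d test volumes\n",
              x$scheme, nrow(x$train), nrow(x$validation), nrow(x$test)))
  invisible(x)
}

plan_cases <- function(cohort, assignment) {
  ids <- vapply(cohort, function(p) p$baseline$patient_id, 1L)
  lapply(seq_len(nrow(assignment)), function(i) {
    p <- cohort[[which(ids == assignment$patient_id[i])]]
    p[[assignment$timepoint[i]]]
  })
}

#' Run the ISD reproducibility study on a synthetic cohort
#'
#' For every volume and inter-slice distance, `n_trials` virtual-observer
#' segmentations are drawn and compared: bifurcation-localization distance,
#' pooled per-slice Dice/Hausdorff by boundary and branch, paired tests of
#' per-volume mean Dice across ISD pairs, and two-way mixed
#' absolute-agreement ICCs of the VWV and of pooled VWT-map cells.
#'
#' @param cases list of `phantom_case` objects (a cohort flattened over
#'   timepoints, or any subset).
#' @param isds inter-slice distances in mm.
#' @param observer an [observer_model()].
#' @param n_trials repeated segmentations per volume and ISD (default 2).
#' @param seed base seed; trial seeds are derived deterministically.
#' @param compare_step common-grid step for slice comparisons in mm.
#' @param grid_spacing raster/SDF pixel size for metrics and volumes.
#' @param include_slices,include_vwv,include_vwt switch off expensive parts.
#' @return object of class `isd_study`.
#' @export
run_isd_study <- function(cases, isds = c(1, 2, 3),
                          observer = observer_model(), n_trials = 2,
                          seed = 1, compare_step = 0.35,
                          grid_spacing = 0.05, include_slices = TRUE,
                          include_vwv = TRUE, include_vwt = TRUE) {
  bif <- list(); slices <- list(); vwv_icc <- list(); vwt_icc <- list()
  vol_mean_dsc <- list()
  for (isd in isds) {
    key <- as.character(isd)
    vwv_mat <- matrix(NA_real_, length(cases), n_trials)
    vwt_cells <- NULL
    for (ci in seq_along(cases)) {
      trials <- lapply(seq_len(n_trials), function(tr)
        virtual_observer(cases[[ci]], isd, observer,
                         trial_seed = seed + 7919L * ci + 104729L * tr +
                           round(1e6 * isd)))
      bif[[length(bif) + 1L]] <- data.frame(
        isd = isd, volume = ci,
        distance = bifurcation_distance(trials[[1L]], trials[[2L]]))
      if (include_slices) {
        cmp <- compare_stacks(trials[[1L]], trials[[2L]],
                              step = compare_step,
                              grid_spacing = grid_spacing)
        cmp$isd <- isd; cmp$volume <- ci
        slices[[length(slices) + 1L]] <- cmp
        for (kind in c("MAB", "LIB"))
          vol_mean_dsc[[length(vol_mean_dsc) + 1L]] <- data.frame(
            isd = isd, volume = ci, kind = kind,
            dsc = mean(cmp$dsc[cmp$kind == kind]))
      }
      if (include_vwv)
        vwv_mat[ci, ] <- vapply(trials, vwv,
                                grid_spacing = grid_spacing, 1)
      if (include_vwt) {
        maps <- lapply(trials, vwt_map, grid_spacing = grid_spacing)
        pr <- map_pairs(maps[[1L]], maps[[2L]])
        vwt_cells <- rbind(vwt_cells, pr)
      }
    }
    if (include_vwv)
      vwv_icc[[key]] <- icc_absolute_agreement(vwv_mat)
    if (include_vwt && !is.null(vwt_cells))
      vwt_icc[[key]] <- icc_absolute_agreement(as.matrix(vwt_cells))
  }
  bif <- do.call(rbind, bif)
  slices <- if (length(slices)) do.call(rbind, slices) else NULL
  vol_mean_dsc <- if (length(vol_mean_dsc)) do.call(rbind, vol_mean_dsc)
  else NULL
  # pooled DSC/HD per (ISD, branch, boundary) - the per-slice distributions
  pooled <- NULL
  if (!is.null(slices)) {
    pooled <- do.call(rbind, lapply(split(
      slices, list(slices$isd, slices$vessel, slices$kind), drop = TRUE),
      function(d) data.frame(isd = d$isd[1L], vessel = d$vessel[1L],
                             kind = d$kind[1L], n = nrow(d),
                             dsc_mean = mean(d$dsc), dsc_sd = sd(d$dsc),
                             hd_mean = mean(d$hd), hd_sd = sd(d$hd))))
    all_rows <- do.call(rbind, lapply(split(
      slices, list(slices$isd, slices$kind), drop = TRUE),
      function(d) data.frame(isd = d$isd[1L], vessel = "ALL",
                             kind = d$kind[1L], n = nrow(d),
                             dsc_mean = mean(d$dsc), dsc_sd = sd(d$dsc),
                             hd_mean = mean(d$hd), hd_sd = sd(d$hd))))
    pooled <- rbind(pooled, all_rows)
    rownames(pooled) <- NULL
  }
  # paired tests of per-volume mean DSC between ISD settings
  isd_tests <- NULL
  if (!is.null(vol_mean_dsc) && length(isds) > 1L) {
    combs <- utils::combn(isds, 2, simplify = FALSE)
    isd_tests <- do.call(rbind, lapply(combs, function(pr) {
      do.call(rbind, lapply(c("MAB", "LIB"), function(kind) {
        a <- vol_mean_dsc[vol_mean_dsc$isd == pr[1L] &
                            vol_mean_dsc$kind == kind, ]
        b <- vol_mean_dsc[vol_mean_dsc$isd == pr[2L] &
                            vol_mean_dsc$kind == kind, ]
        m <- merge(a, b, by = "volume")
        res <- tryCatch(normality_gated_paired_test(m$dsc.x, m$dsc.y),
                        error = function(e) list(test = "degenerate",
                                                 p_value = NA_real_))
        data.frame(isd_a = pr[1L], isd_b = pr[2L], kind = kind,
                   test = res$test, p_value = res$p_value)
      }))
    }))
  }
  bif_summary <- aggregate(distance ~ isd, bif, function(v)
    c(mean = mean(v), sd = sd(v)))
  structure(list(bifurcation = bif, bifurcation_summary = bif_summary,
                 slices = slices, pooled = pooled, isd_tests = isd_tests,
                 vwv_icc = vwv_icc, vwt_icc = vwt_icc,
                 seed = seed, isds = isds),
            class = "isd_study")
}

#' @export
print.isd_study <- function(x, ...) {
  cat("ISD reproducibility study\n")
  cat("  mean bifurcation distance (mm) by ISD:\n")
  bs <- x$bifurcation_summary
  for (i in seq_len(nrow(bs)))
    cat(sprintf("    ISD %g mm: %.3f (SD %.3f)\n", bs$isd[i],
                bs$distance[i, "mean"], bs$distance[i, "sd"]))
  if (!is.null(x$pooled)) {
    cat("  pooled slice-wise DSC (ALL):\n")
    a <- x$pooled[x$pooled$vessel == "ALL", ]
    for (i in seq_len(nrow(a)))
      cat(sprintf("    ISD %g mm %s: DSC %.4f (SD %.4f), HD %.3f mm\n",
                  a$isd[i], a$kind[i], a$dsc_mean[i], a$dsc_sd[i],
                  a$hd_mean[i]))
  }
  for (k in names(x$vwv_icc))
    cat(sprintf("  VWV ICC at ISD %s mm: %.3f [%.3f, %.3f]\n", k,
                x$vwv_icc[[k]]$icc, x$vwv_icc[[k]]$ci_lower,
                x$vwv_icc[[k]]$ci_upper))
  for (k in names(x$vwt_icc))
    cat(sprintf("  VWT ICC at ISD %s mm: %.3f [%.3f, %.3f]\n", k,
                x$vwt_icc[[k]]$icc, x$vwt_icc[[k]]$ci_lower,
                x$vwt_icc[[k]]$ci_upper))
  invisible(x)
}

# train one network on the plan's training volumes and evaluate it on the
# test volumes: per-slice comparison vs truth + VWV/VWT measurements
eval_scheme <- function(cohort, plan, isd, train_config, compare_step,
                        grid_spacing, n_eval, include_vwt) {
  train_cases <- plan_cases(cohort, plan$train)
  test_cases <- plan_cases(cohort, plan$test)
  if (!is.null(n_eval) && length(test_cases) > n_eval)
    test_cases <- test_cases[seq_len(n_eval)]
  size <- train_config$input_size
  if (is.null(size)) size <- c(192L, 256L)
  model <- if (!is.null(train_config$model)) train_config$model else {
    samples <- do.call(c, lapply(train_cases, function(cs)
      make_slide_samples(cs, truth_stack(cs$geometry, isd),
                         reslice_step = train_config$reslice_step,
                         size = size,
                         slice_stride = train_config$slice_stride)))
    do.call(unet_fit, c(list(samples = samples), train_config$fit_args))
  }
  slices <- list(); meas <- list()
  for (ci in seq_along(test_cases)) {
    cs <- test_cases[[ci]]
    ok <- tryCatch({
      manual <- truth_stack(cs$geometry, isd)
      auto <- segment_volume(model, cs$volume, cs$bifurcation_z,
                             ica_boxes = truth_ica_boxes(cs, isd), isd = isd,
                             size = size)
      cmp <- compare_stacks(auto, manual, step = compare_step,
                            grid_spacing = grid_spacing)
      cmp$volume <- ci
      slices[[ci]] <- cmp
      row <- data.frame(
        volume = ci,
        vwv_auto = vwv(auto, grid_spacing = grid_spacing),
        vwv_manual = vwv(manual, grid_spacing = grid_spacing),
        vwt_auto = NA_real_, vwt_manual = NA_real_)
      if (include_vwt) {
        row$vwt_auto <- map_summary(vwt_map(auto,
                                            grid_spacing = grid_spacing))
        row$vwt_manual <- map_summary(vwt_map(manual,
                                              grid_spacing = grid_spacing))
      }
      meas[[ci]] <- row
      TRUE
    }, error = function(e) {
      warning(sprintf("test volume %d failed: %s", ci,
                      conditionMessage(e)))
      FALSE
    })
    if (!ok) next
  }
  if (length(slices) == 0L) stop("no test volume could be evaluated")
  slices <- do.call(rbind, slices)
  list(model = model, slices = slices, strata = stratify_comparison(slices),
       measurements = do.call(rbind, meas))
}

#' Run the partition-strategy study on a synthetic cohort
#'
#' Trains one network per partition scheme (patient-based and time-based)
#' with shared seeds, segments the common test set, and reports stratified
#' Dice/Hausdorff tables, a paired test of per-slice Dice between the
#' schemes, and VWV/VWT agreement with the manual (ground-truth)
#' measurements (signed/absolute differences, Pearson r, Bland-Altman).
#'
#' @param cohort from [sample_cohort()] (rendered volumes required).
#' @param isd working inter-slice distance of the manual segmentations and
#'   the algorithm output in mm (the study setting is 2).
#' @param train_config list with `reslice_step`, `slice_stride`, and
#'   `fit_args` passed to [unet_fit()].
#' @param seed seed for the partition shuffle and training.
#' @param compare_step,grid_spacing metric resolution settings.
#' @param n_eval_volumes cap on the number of evaluated test volumes
#'   (`NULL` evaluates all).
#' @param include_vwt compute VWT maps (the slowest part of evaluation).
#' @return object of class `partition_study`.
#' @export
run_partition_study <- function(cohort, isd = 2,
                                train_config = partition_train_config(),
                                seed = 1, compare_step = 0.35,
                                grid_spacing = 0.05,
                                n_eval_volumes = NULL,
                                include_vwt = TRUE) {
  train_config$fit_args$seed <- seed
  res <- list()
  for (scheme in c("patient_based", "time_based")) {
    plan <- make_partition(cohort, scheme, seed = seed)
    res[[scheme]] <- tryCatch(
      eval_scheme(cohort, plan, isd, train_config, compare_step,
                  grid_spacing, n_eval_volumes, include_vwt),
      error = function(e) {
        warning(sprintf("scheme %s failed: %s", scheme, conditionMessage(e)))
        NULL
      })
  }
  # paired per-slice DSC between schemes on the common test slices
  scheme_tests <- NULL; agreement <- list()
  if (!is.null(res$patient_based) && !is.null(res$time_based)) {
    a <- res$patient_based$slices; b <- res$time_based$slices
    m <- merge(a, b, by = c("volume", "z", "kind"))
    scheme_tests <- do.call(rbind, lapply(c("MAB", "LIB"), function(kind) {
      d <- m[m$kind == kind, ]
      res_t <- tryCatch(normality_gated_paired_test(d$dsc.x, d$dsc.y),
                        error = function(e) list(test = "degenerate",
                                                 p_value = NA_real_))
      data.frame(kind = kind, n = nrow(d),
                 dsc_patient = mean(d$dsc.x), dsc_time = mean(d$dsc.y),
                 test = res_t$test, p_value = res_t$p_value)
    }))
    for (scheme in names(res)) {
      mm <- res[[scheme]]$measurements
      if (is.null(mm) || nrow(mm) < 2L) next
      agreement[[scheme]] <- list(
        vwv = list(delta = delta_summary(mm$vwv_auto, mm$vwv_manual),
                   pearson = if (nrow(mm) >= 3L)
                     tryCatch(pearson(mm$vwv_manual, mm$vwv_auto),
                              error = function(e) NULL) else NULL,
                   bland_altman = bland_altman(mm$vwv_manual, mm$vwv_auto)),
        vwt = if (all(is.finite(mm$vwt_auto))) list(
          delta = delta_summary(mm$vwt_auto, mm$vwt_manual),
          pearson = if (nrow(mm) >= 3L)
            tryCatch(pearson(mm$vwt_manual, mm$vwt_auto),
                     error = function(e) NULL) else NULL,
          bland_altman = bland_altman(mm$vwt_manual, mm$vwt_auto)) else NULL)
    }
  }
  structure(list(schemes = res, scheme_tests = scheme_tests,
                 agreement = agreement, isd = isd, seed = seed),
            class = "partition_study")
}

#' Training configuration for the partition study
#'
#' The default reslicing step of 0.5 mm mirrors the augmentation protocol;
#' scaled-down runs typically pass `reslice_step` equal to the working ISD
#' (no interpolation) and fewer epochs.
#'
#' @param reslice_step,slice_stride training-slice construction settings.
#' @param input_size network input `c(rows, cols)`; the protocol size
#'   192 x 256 by default, halvable for scaled-down comparison runs.
#' @param model optional pre-fitted model (or `function(image, z)` oracle)
#'   substituted for both schemes instead of training.
#' @param ... overrides for the [unet_fit()] arguments.
#' @return configuration list.
#' @export
partition_train_config <- function(reslice_step = 0.5, slice_stride = 1,
                                   input_size = c(192L, 256L),
                                   model = NULL, ...) {
  fit_args <- utils::modifyList(
    list(depth = 3, width_mult = 0.25, epochs = 2, batch_size = 4,
         lr = 1e-2, warmup_epochs = 1, verbose = FALSE),
    list(...))
  list(reslice_step = reslice_step, slice_stride = slice_stride,
       input_size = as.integer(input_size), model = model,
       fit_args = fit_args)
}

#' @export
print.partition_study <- function(x, ...) {
  cat(sprintf("Partition-strategy study (working ISD %g mm)\n", x$isd))
  for (scheme in names(x$schemes)) {
    s <- x$schemes[[scheme]]
    if (is.null(s)) { cat(sprintf("  %s: failed\n", scheme)); next }
    ov <- s$strata[s$strata$stratum == "Overall", ]
    for (i in seq_len(nrow(ov)))
      cat(sprintf("  %s %s: DSC %.4f (SD %.4f), HD %.3f mm (n=%d slices)\n",
                  scheme, ov$kind[i], ov$dsc_mean[i], ov$dsc_sd[i],
                  ov$hd_mean[i], ov$n[i]))
  }
  if (!is.null(x$scheme_tests)) {
    for (i in seq_len(nrow(x$scheme_tests))) {
      r <- x$scheme_tests[i, ]
      cat(sprintf("  %s: patient %.4f vs time %.4f (%s p=%.3g)\n",
                  r$kind, r$dsc_patient, r$dsc_time, r$test, r$p_value))
    }
  }
  invisible(x)
}
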