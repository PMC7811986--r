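# Config-driven orchestration: enumerate (path x frequency x voltage)
# scenarios, pick the body-model mode, run the solves, and emit dose and
# HCF tables with provenance. Campaign outputs are a pure function of the
# configuration (no randomness anywhere in the pipeline).

#' Define a simulation campaign
#'
#' Defaults reproduce the standard scenario grid: the 16 IEC current paths
#' at DC, 50 Hz, 1 kHz, 10 kHz and 100 kHz. HCF campaigns
#' (`purpose = "hcf"`) force Intern-BM mode for every solve (the skin
#' impedance has no influence on the HCF); impedance campaigns honor the
#' regime classification of [select_body_model()] under the `"auto"` policy,
#' and scenarios classified `CASE_BY_CASE` are skipped with a logged warning
#' unless a mode is forced.
#'
#' @param phantom A prebuilt `voxel_phantom`, or `NULL` to build from
#'   `config`.
#' @param config A [phantom_config()] (used when `phantom` is `NULL`).
#' @param paths Character vector of path labels (wildcards allowed).
#' @param frequencies Frequencies in Hz.
#' @param touch_voltages Touch voltages in V.
#' @param mode_policy `"auto"`, `"TOTAL"` or `"INTERN"`.
#' @param purpose `"hcf"` (forces INTERN, computes the HCF table; requires
#'   the reference path) or `"impedance"`.
#' @param reference Reference path for HCF normalization.
#' @param tissues Tissue dielectric table.
#' @param tolerance,max_iter Solver settings.
#' @param n_planes Cross-section planes for the body-current integral.
#' @param out_dir Output directory (`NULL` = in-memory only). Completed
#'   solves found in `out_dir` are reused on rerun (idempotent).
#' @return A list of class `campaign`.
#' @export
campaign <- function(phantom = NULL, config = phantom_config(),
                     paths = IEC_PATHS,
                     frequencies = c(0, 50, 1e3, 1e4, 1e5),
                     touch_voltages = 100,
                     mode_policy = c("auto", "TOTAL", "INTERN"),
                     purpose = c("hcf", "impedance"),
                     reference = "LH-BF",
                     tissues = default_tissue_table(),
                     tolerance = 1e-9, max_iter = 400, n_planes = 4L,
                     out_dir = NULL) {
  mode_policy <- match.arg(mode_policy)
  purpose <- match.arg(purpose)
  pth <- expand_paths(paths)
  if (purpose == "hcf" && !reference %in% pth$label) {
    stop("HCF campaign requires the reference path '", reference, "'")
  }
  structure(
    list(phantom = phantom, config = config, paths = pth,
         frequencies = frequencies, touch_voltages = touch_voltages,
         mode_policy = mode_policy, purpose = purpose, reference = reference,
         tissues = tissues, tolerance = tolerance, max_iter = max_iter,
         n_planes = n_planes, out_dir = out_dir),
    class = "campaign"
  )
}

.campaign_phantom <- function(cmp) {
  if (!is.null(cmp$phantom)) cmp$phantom else build_phantom(cmp$config)
}

.scenario_key <- function(cmp, label, f, v, mode) {
  rlang::hash(list(
    config = if (is.null(cmp$phantom)) unclass(cmp$config) else
      list(labels_hash = rlang::hash(cmp$phantom$labels),
           spacing = cmp$phantom$spacing),
    tissues = as.data.frame(cmp$tissues[c("tissue", "mode", "sigma_dc", "eps_inf")]),
    terms = cmp$tissues$terms,
    label = label, frequency = f, voltage = v, mode = mode,
    tolerance = cmp$tolerance, n_planes = cmp$n_planes
  ))
}

#' Run a campaign
#'
#' One solve per (path, frequency, voltage); Cholesky preconditioners are
#' reused across frequencies of the same path. With `out_dir` set, each
#' completed solve is written to `out_dir/solves/<hash>.json` and reruns
#' with an identical configuration reuse those results (bit-identical
#' tables). Failed solves are recorded and the campaign continues.
#'
#' @param cmp A [campaign()].
#' @param quiet Suppress per-solve progress messages.
#' @return A `campaign_result`: `dose` tibble, `hcf` table (HCF purpose),
#'   `skipped` and `failures` tibbles, and the effective configuration.
#' @export
run_campaign <- function(cmp, quiet = TRUE) {
  stopifnot(inherits(cmp, "campaign"))
  ph <- .campaign_phantom(cmp)
  solve_dir <- NULL
  if (!is.null(cmp$out_dir)) {
    solve_dir <- file.path(cmp$out_dir, "solves")
    dir.create(solve_dir, recursive = TRUE, showWarnings = FALSE)
  }
  grid <- expand.grid(frequency = cmp$frequencies,
                      voltage = cmp$touch_voltages,
                      i_path = seq_len(nrow(cmp$paths)),
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$i_path, grid$frequency, grid$voltage), ]
  rows <- list(); skipped <- list(); failures <- list()
  # the factor is reused across frequencies/voltages of one path and dropped
  # when the path changes (it is large)
  pc <- NULL; pc_key <- ""

  for (r in seq_len(nrow(grid))) {
    label <- cmp$paths$label[[grid$i_path[r]]]
    f <- grid$frequency[r]; v <- grid$voltage[r]
    mode <- if (cmp$purpose == "hcf") "INTERN"
    else if (cmp$mode_policy == "auto") select_body_model(f, v)
    else cmp$mode_policy
    if (mode == "CASE_BY_CASE") {
      warning("scenario ", label, " @ ", f, " Hz, ", v,
              " V is classified CASE_BY_CASE; skipped (force a mode to run it)")
      skipped[[length(skipped) + 1L]] <- tibble::tibble(
        path = label, frequency = f, touch_voltage = v, reason = "CASE_BY_CASE")
      next
    }
    key <- .scenario_key(cmp, label, f, v, mode)
    cache_file <- if (!is.null(solve_dir)) file.path(solve_dir, paste0(key, ".json"))
    if (!is.null(cache_file) && file.exists(cache_file)) {
      rows[[length(rows) + 1L]] <- tibble::as_tibble(
        jsonlite::fromJSON(cache_file))
      next
    }
    if (!quiet) message("solving ", label, " @ ", f, " Hz, ", v, " V [", mode, "]")
    res <- tryCatch({
      sc <- contact_scenario(label, f, v, mode)
      this_key <- paste(label, mode)
      if (this_key != pc_key) { pc <- NULL; pc_key <- this_key }
      sol <- solve_scenario(ph, cmp$tissues, sc, tolerance = cmp$tolerance,
                            max_iter = cmp$max_iter, precond = pc,
                            keep_precond = TRUE)
      pc <- sol$precond
      sol$precond <- NULL
      compute_dose(sol, cmp$n_planes)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <- tibble::tibble(
        path = label, frequency = f, touch_voltage = v,
        error = conditionMessage(res))
      next
    }
    if (!is.null(cache_file)) {
      jsonlite::write_json(res, cache_file, auto_unbox = TRUE, digits = NA,
                           dataframe = "rows")
    }
    rows[[length(rows) + 1L]] <- res
  }
  dose <- dplyr::bind_rows(rows)
  hcf <- if (cmp$purpose == "hcf" && nrow(dose)) {
    hcf_table(dose, cmp$reference)
  } else NULL
  out <- structure(
    list(dose = dose, hcf = hcf,
         skipped = dplyr::bind_rows(skipped), failures = dplyr::bind_rows(failures),
         campaign = cmp),
    class = "campaign_result"
  )
  if (!is.null(cmp$out_dir)) {
    write_dose_report(dose, file.path(cmp$out_dir, "dose"))
    if (!is.null(hcf)) write_hcf_table(hcf, file.path(cmp$out_dir, "hcf"))
    prov <- list(
      config_hash = rlang::hash(list(unclass(cmp$config), cmp$paths$label,
                                     cmp$frequencies, cmp$touch_voltages,
                                     cmp$mode_policy, cmp$purpose)),
      n_solves = nrow(dose), n_failed = length(failures),
      residual_max = if (nrow(dose)) max(dose$residual) else NA,
      timestamp = format(Sys.time(), tz = "UTC")
    )
    jsonlite::write_json(prov, file.path(cmp$out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (nrow(out$failures)) {
    warning(nrow(out$failures), " scenario solve(s) failed; see $failures")
  }
  out
}

#' @export
print.campaign_result <- function(x, ...) {
  cat("<campaign_result> ", nrow(x$dose), " solve(s), ",
      nrow(x$skipped), " skipped, ", nrow(x$failures), " failed\n", sep = "")
  if (!is.null(x$hcf)) print(hcf_wide(x$hcf), n = 20)
  invisible(x)
}

#' Sensitivity sweeps: electrode position and tissue conductivity
#'
#' Reruns the campaign's affected scenarios over a sweep grid and reports
#' per-scenario deltas of the per-unit-current heart field (E99Heart /
#' |I_Body|) and of the HCF against the unswept baseline. A zero offset or a
#' scale factor of 1 reproduces the baseline exactly (deterministic
#' pipeline). Offsets that move an electrode off the body surface are
#' flagged and the sweep continues.
#'
#' @param cmp A [campaign()].
#' @param type `"tissue_sigma_scale"` or `"electrode_offset"`.
#' @param tissue Tissue name(s) whose `sigma_dc` is scaled.
#' @param factors Scale factors (tissue sweep).
#' @param site Electrode site to move (offset sweep).
#' @param offsets_mm Numeric matrix (n x 3) of offsets in mm.
#' @param baseline Optional precomputed baseline `campaign_result`.
#' @return A `sweep_result`: tibble with one row per (sweep point, path,
#'   frequency) holding the swept and baseline metrics, plus a `flagged`
#'   tibble of rejected sweep points.
#' @export
sensitivity_sweep <- function(cmp, type = c("tissue_sigma_scale", "electrode_offset"),
                              tissue = NULL, factors = NULL,
                              site = NULL, offsets_mm = NULL,
                              baseline = NULL) {
  type <- match.arg(type)
  if (is.null(baseline)) baseline <- run_campaign(cmp)
  base <- dplyr::transmute(baseline$dose, path = .data$path,
                           frequency = .data$frequency,
                           base_e99_per_i = .data$e99_heart / .data$i_body_a)
  if (!is.null(baseline$hcf)) {
    base <- dplyr::left_join(
      base, dplyr::select(tibble::as_tibble(baseline$hcf),
                          "path", "frequency", base_f99 = "f99"),
      by = c("path", "frequency"))
  }
  rows <- list(); flagged <- list()
  if (type == "tissue_sigma_scale") {
    stopifnot(!is.null(tissue), !is.null(factors))
    for (fac in factors) {
      tt <- cmp$tissues
      sel <- tt$tissue %in% tissue
      if (!any(sel)) stop("unknown tissue(s): ", paste(tissue, collapse = ", "))
      tt$sigma_dc[sel] <- tt$sigma_dc[sel] * fac
      cmp2 <- cmp; cmp2$tissues <- tt; cmp2$out_dir <- NULL
      res <- run_campaign(cmp2)
      rows[[length(rows) + 1L]] <- .sweep_join(res, base, sweep_value = fac)
    }
  } else {
    stopifnot(!is.null(site), !is.null(offsets_mm))
    offsets_mm <- rbind(offsets_mm)
    ph0 <- .campaign_phantom(cmp)
    affected <- cmp$paths$label[purrr::map_lgl(
      seq_len(nrow(cmp$paths)),
      function(i) site %in% c(cmp$paths$source_sites[[i]], cmp$paths$sink_sites[[i]]))]
    keep <- union(affected, cmp$reference)
    for (r in seq_len(nrow(offsets_mm))) {
      off <- offsets_mm[r, ]
      ph <- tryCatch(shift_electrode_site(ph0, site, off),
                     electrode_off_surface = function(e) e)
      if (inherits(ph, "condition")) {
        flagged[[length(flagged) + 1L]] <- tibble::tibble(
          sweep_value = paste(off, collapse = "/"),
          reason = conditionMessage(ph))
        next
      }
      cmp2 <- cmp; cmp2$phantom <- ph; cmp2$out_dir <- NULL
      cmp2$paths <- cmp$paths[cmp$paths$label %in% keep, ]
      res <- run_campaign(cmp2)
      rows[[length(rows) + 1L]] <- .sweep_join(
        res, base, sweep_value = sqrt(sum(off^2)) * sign(sum(off)))
    }
  }
  structure(list(results = dplyr::bind_rows(rows),
                 flagged = dplyr::bind_rows(flagged), type = type),
            class = "sweep_result")
}

.sweep_join <- function(res, base, sweep_value) {
  out <- dplyr::transmute(res$dose, path = .data$path, frequency = .data$frequency,
                          e99_per_i = .data$e99_heart / .data$i_body_a)
  if (!is.null(res$hcf)) {
    out <- dplyr::left_join(
      out, dplyr::select(tibble::as_tibble(res$hcf), "path", "frequency", "f99"),
      by = c("path", "frequency"))
  }
  out <- dplyr::left_join(out, base, by = c("path", "frequency"))
  out$delta_e99_per_i <- out$e99_per_i - out$base_e99_per_i
  if (all(c("f99", "base_f99") %in% names(out))) {
    out$delta_f99 <- out$f99 - out$base_f99
  }
  dplyr::bind_cols(tibble::tibble(sweep_value = sweep_value), out)
}
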