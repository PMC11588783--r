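#' Configuration of an evaluation run
#'
#' Collects every knob of the split-and-score pipeline in one serializable
#' object. A run's configuration is written verbatim into its output
#' directory, which together with the seed makes any report bundle
#' reproducible byte for byte.
#'
#' Input can be a set of generated phantoms (`mode = "phantom"`) or
#' directories of matched image / ground-truth / prediction files
#' (`mode = "files"`; cases are matched by file name across directories).
#'
#' @param mode `"phantom"` or `"files"`.
#' @param n_cases number of phantom cases to generate.
#' @param phantom a [phantom_spec()] (phantom mode); its seed field is
#'   re-derived per case from `seed`.
#' @param error_model,magnitude simulated prediction degradation applied to
#'   the ground truth in phantom mode (see [simulate_prediction()]);
#'   `magnitude = 0` scores the ground truth against itself.
#' @param image_dir,gt_dir,pred_dir directories for `mode = "files"`.
#' @param edge an [edge_params()].
#' @param tolerance_radius border-split tolerance, voxels (see
#'   [split_border()]).
#' @param match_tolerance true-positive match radius, voxels (see
#'   [tp_decomposition()]).
#' @param nsd_tau NSD tolerance in mm (`NULL`: 1 voxel).
#' @param out_dir output directory for the report bundle.
#' @param seed master seed for the run.
#' @return An object of class `us_run_config` (a named list).
#' @export
run_config <- function(mode = c("phantom", "files"), n_cases = 10L,
                       phantom = phantom_spec(),
                       error_model = "dilate", magnitude = 0,
                       image_dir = NULL, gt_dir = NULL, pred_dir = NULL,
                       edge = edge_params(), tolerance_radius = 1L,
                       match_tolerance = 1L, nsd_tau = NULL,
                       out_dir = tempfile("usborder_run_"), seed = 1L) {
  mode <- match.arg(mode)
  structure(
    list(mode = mode, n_cases = as.integer(n_cases), phantom = phantom,
         error_model = error_model, magnitude = magnitude,
         image_dir = image_dir, gt_dir = gt_dir, pred_dir = pred_dir,
         edge = edge, tolerance_radius = as.integer(tolerance_radius),
         match_tolerance = as.integer(match_tolerance), nsd_tau = nsd_tau,
         out_dir = out_dir, seed = as.integer(seed)),
    class = "us_run_config"
  )
}

config_to_yaml <- function(config, path) {
  ser <- rapply(unclass(config), f = function(x) x, how = "replace")
  yaml::write_yaml(ser, path)
}

resolve_cases <- function(config) {
  if (config$mode == "phantom") {
    lapply(seq_len(config$n_cases), function(i) {
      ph <- generate_phantom(
        phantom_update(config$phantom, seed = derive_seed(config$seed, i)))
      pred <- if (config$magnitude > 0) {
        simulate_prediction(ph$labels, config$error_model,
                            config$magnitude,
                            seed = derive_seed(config$seed, 100000L + i))
      } else ph$labels
      list(case_id = sprintf("phantom_%03d", i), image = ph$image,
           gt = ph$labels, pred = pred)
    })
  } else {
    ids_gt <- list.files(config$gt_dir)
    ids_img <- list.files(config$image_dir)
    ids_pred <- list.files(config$pred_dir)
    common <- Reduce(intersect, list(ids_gt, ids_img, ids_pred))
    skipped <- setdiff(union(union(ids_gt, ids_img), ids_pred), common)
    if (length(skipped) > 0) {
      warning("run_evaluation: skipping unmatched case files: ",
              paste(skipped, collapse = ", "), call. = FALSE)
    }
    if (length(common) == 0) {
      stop("run_evaluation: no matched image/label/prediction triples",
           call. = FALSE)
    }
    lapply(sort(common), function(fn) {
      list(case_id = sub("\\.nii(\\.gz)?$|\\.mh[da]$|\\.png$", "", fn),
           image = read_volume(file.path(config$image_dir, fn), "image"),
           gt = read_volume(file.path(config$gt_dir, fn), "label"),
           pred = read_volume(file.path(config$pred_dir, fn), "label"))
    })
  }
}

#' Run the full border evaluation and write a report bundle
#'
#' For every case: computes the edge map of the image, extracts and splits
#' each ground-truth class border into distinct/completed, scores the
#' prediction with Dice/HD95/NSD and with the true-positive border
#' decomposition, and writes the bundle: `metrics_table.csv` (per case and
#' class: dice, hd95_mm, nsd) and `split_table.csv` (reference fractions
#' and B_TP/B_Distinct/B_Completed percentages), both human-rounded to 3
#' decimals; `cases.json` with full-precision rows; `aggregates.json` with
#' per-class mean and sample sd; `config.yaml`; `run.log`. Per-case rows
#' are keyed by (case_id, class_id); aggregates live in a separate file so
#' re-aggregation stays possible.
#'
#' @param config a [run_config()] or path to a YAML file of its fields.
#' @return Invisibly, `list(metrics, split, aggregates, out_dir,
#'   validation)`; the tibbles are full precision.
#' @export
run_evaluation <- function(config) {
  if (is.character(config)) {
    raw <- yaml::read_yaml(config)
    if (!is.null(raw$phantom)) raw$phantom <- do.call(phantom_spec,
                                                      raw$phantom)
    if (!is.null(raw$edge)) raw$edge <- do.call(edge_params, raw$edge)
    config <- do.call(run_config, raw)
  }
  stopifnot(inherits(config, "us_run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  log_line <- function(...) cat(sprintf(...), "\n", sep = "",
                                file = log_path, append = TRUE)
  cat("", file = log_path)
  log_line("usborder run, seed %d, mode %s", config$seed, config$mode)

  cases <- resolve_cases(config)
  log_line("%d cases resolved", length(cases))

  metrics <- list(); split_rows <- list()
  for (cs in cases) {
    edges <- compute_edge_map(cs$image, config$edge)
    splits <- split_all_classes(cs$gt, edges,
                                tolerance_radius = config$tolerance_radius)
    rows <- purrr::map_dfr(splits, function(sp) {
      pb <- extract_border(cs$pred, sp$class_id)
      tp_decomposition(sp, pb, match_tolerance = config$match_tolerance)
    })
    rows$case_id <- cs$case_id
    split_rows[[cs$case_id]] <- dplyr::relocate(rows, "case_id")
    metrics[[cs$case_id]] <- case_metrics(cs$pred, cs$gt,
                                          nsd_tau = config$nsd_tau,
                                          case_id = cs$case_id)
    stopifnot(all(abs(rows$tp_distinct_pct + rows$tp_completed_pct -
                        rows$tp_total_pct) < 1e-9))
  }
  metrics <- dplyr::bind_rows(metrics)
  split_tbl <- dplyr::bind_rows(split_rows)

  agg <- list(
    metrics = aggregate_metrics(metrics, by = "class_id"),
    split = aggregate_metrics(
      dplyr::select(split_tbl, -"match_tolerance"), by = "class_id")
  )
  round3 <- function(df) {
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], round, digits = 3)
    df
  }
  readr::write_csv(round3(metrics),
                   file.path(config$out_dir, "metrics_table.csv"))
  readr::write_csv(round3(split_tbl),
                   file.path(config$out_dir, "split_table.csv"))
  jsonlite::write_json(
    list(metrics = metrics, split = split_tbl),
    file.path(config$out_dir, "cases.json"), digits = NA, dataframe = "rows")
  jsonlite::write_json(agg, file.path(config$out_dir, "aggregates.json"),
                       digits = NA, dataframe = "rows")
  config_to_yaml(config, file.path(config$out_dir, "config.yaml"))
  val <- validate_report(config$out_dir)
  log_line("validation: %s", if (val$pass) "pass" else "FAIL")
  if (!val$pass) {
    stop("run_evaluation: emitted bundle failed validation", call. = FALSE)
  }
  log_line("bundle written to %s", config$out_dir)
  invisible(list(metrics = metrics, split = split_tbl, aggregates = agg,
                 out_dir = config$out_dir, validation = val))
}

#' Re-check the invariants of a report bundle
#'
#' Reads `metrics_table.csv` and `split_table.csv` from a bundle directory
#' and re-verifies, from the CSVs alone: value ranges (Dice/NSD in [0,1],
#' HD95 >= 0, percentages in [0,100]), the exact complement of the
#' reference fractions, and the additivity of the true-positive
#' decomposition, each up to the 3-decimal rounding of the human tables.
#'
#' @param path bundle directory written by [run_evaluation()].
#' @return `list(pass = logical, findings = tibble)`; `findings` names the
#'   offending file, row and check for every violation.
#' @export
validate_report <- function(path) {
  if (!dir.exists(path)) {
    stop("validate_report: no such bundle directory: ", path, call. = FALSE)
  }
  mt_path <- file.path(path, "metrics_table.csv")
  sp_path <- file.path(path, "split_table.csv")
  if (!file.exists(mt_path) || !file.exists(sp_path)) {
    stop("validate_report: bundle is missing its CSV tables", call. = FALSE)
  }
  findings <- list()
  note <- function(file, row, check) {
    findings[[length(findings) + 1L]] <<-
      tibble::tibble(file = file, row = row, check = check)
  }
  tol <- 2e-3   # two 3-decimal roundings

  mt <- readr::read_csv(mt_path, show_col_types = FALSE)
  for (i in seq_len(nrow(mt))) {
    if (!is.na(mt$dice[i]) && (mt$dice[i] < 0 || mt$dice[i] > 1)) {
      note("metrics_table.csv", i, "dice outside [0,1]")
    }
    if (!is.na(mt$nsd[i]) && (mt$nsd[i] < 0 || mt$nsd[i] > 1)) {
      note("metrics_table.csv", i, "nsd outside [0,1]")
    }
    if (!is.na(mt$hd95_mm[i]) && mt$hd95_mm[i] < 0) {
      note("metrics_table.csv", i, "hd95 negative")
    }
  }
  sp <- readr::read_csv(sp_path, show_col_types = FALSE)
  pct_cols <- c("reference_distinct_pct", "reference_completed_pct",
                "tp_total_pct", "tp_distinct_pct", "tp_completed_pct")
  for (i in seq_len(nrow(sp))) {
    for (cc in pct_cols) {
      v <- sp[[cc]][i]
      if (!is.na(v) && (v < -tol || v > 100 + tol)) {
        note("split_table.csv", i, paste(cc, "outside [0,100]"))
      }
    }
    if (abs(sp$reference_distinct_pct[i] + sp$reference_completed_pct[i] -
            100) > tol) {
      note("split_table.csv", i, "reference fractions do not sum to 100")
    }
    if (abs(sp$tp_distinct_pct[i] + sp$tp_completed_pct[i] -
            sp$tp_total_pct[i]) > tol) {
      note("split_table.csv", i,
           "tp_distinct + tp_completed != tp_total")
    }
  }
  findings <- if (length(findings) > 0) dplyr::bind_rows(findings) else
    tibble::tibble(file = character(), row = integer(), check = character())
  list(pass = nrow(findings) == 0, findings = findings)
}
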