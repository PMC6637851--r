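# End-to-end orchestration: pose metrics -> fingerprints -> field QSAR,
# driven by a single config (R list or YAML file), with a reproducible
# run report.

.default_config <- function() {
  list(
    paths = list(protein = NULL, poses = NULL, activities = NULL,
                 reference = NULL),
    stages = list(rmsd = TRUE, ifp = TRUE, qsar = TRUE),
    rmsd = list(ring_relaxed = FALSE),
    ifp = list(),                      # overrides for ifp_config()
    fields = list(spacing = 1.0, padding = 5.0, dielectric = "r"),
    pretreat = list(cap = 30, zero_threshold = 0.05, nlevel_max = 4),
    qsar = list(ncomp_max = 8, field_sets = c("S", "E", "SE"),
                srd = FALSE, n_test = NULL),
    contours = list(percentile = 0.85),
    seed = 1L,
    output = "fieldsar_out")
}

# deep-merge user config over defaults, rejecting unknown keys
.merge_config <- function(user, defaults = .default_config(),
                          path = character()) {
  for (k in names(user)) {
    if (!k %in% names(defaults))
      stop("unknown config key: ", paste(c(path, k), collapse = "."))
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])) &&
        is.list(user[[k]])) {
      defaults[[k]] <- .merge_config(user[[k]], defaults[[k]], c(path, k))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Run the post-docking analysis pipeline
#'
#' Executes the enabled stages in order on a set of docked poses:
#' common-graph RMSD versus a reference pose (`rmsd.csv`), per-residue
#' interaction-fingerprint occurrence (`ifp_occurrence.csv` and the
#' long-format `ifp_bits.csv`), and the field-QSAR model
#' (`model.json`, `predictions.csv`, `contours/*.dx`).  Every resolved
#' parameter and the seed are recorded in `run.log` and returned, so a
#' rerun with the same config and inputs reproduces the outputs.
#'
#' @param config Either a named list (see Details) or a YAML file path.
#'   Keys: `paths` (`protein`, `poses`, `activities`, `reference`),
#'   `stages` (`rmsd`, `ifp`, `qsar` toggles), per-stage parameter
#'   blocks `rmsd`, `ifp`, `fields`, `pretreat`, `qsar`, `contours`,
#'   plus `seed` and `output`.
#' @return Invisibly, a list with the resolved `config`, per-stage
#'   results, and output file paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .merge_config(config)
  out_dir <- cfg$output
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- c(paste("fieldsar pipeline run"),
                 paste("resolved config:"),
                 utils::capture.output(utils::str(cfg)))
  result <- list(config = cfg, outputs = character(0))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(log_lines, paste("FAILED at stage:", name),
                   conditionMessage(e)), log_path)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  poses <- stage("load", {
    if (is.null(cfg$paths$poses)) stop("paths$poses is required")
    read_sdf(cfg$paths$poses)
  })
  acts <- if (!is.null(cfg$paths$activities))
    stage("load", read_activity_table(cfg$paths$activities)) else NULL

  if (isTRUE(cfg$stages$rmsd)) {
    result$rmsd <- stage("rmsd", {
      ref <- if (!is.null(cfg$paths$reference))
        read_sdf(cfg$paths$reference)[[1]] else poses[[1]]
      tab <- rmsd_table(ref, poses,
                        ring_relaxed = isTRUE(cfg$rmsd$ring_relaxed))
      p <- file.path(out_dir, "rmsd.csv")
      utils::write.csv(tab, p, row.names = FALSE)
      result$outputs <- c(result$outputs, p)
      tab
    })
  }

  if (isTRUE(cfg$stages$ifp)) {
    result$ifp <- stage("ifp", {
      if (is.null(cfg$paths$protein))
        stop("paths$protein is required for the ifp stage")
      protein <- read_protein(cfg$paths$protein)
      icfg <- do.call(ifp_config, cfg$ifp)
      ifps <- lapply(poses, function(m)
        compute_ifp(complex_pose(protein, m), icfg))
      long <- do.call(rbind, lapply(seq_along(ifps), function(i) {
        f <- ifps[[i]]
        if (!nrow(f)) return(NULL)
        bits <- c("C", "B", "S", "P", "H", "A", "D", "Ar", "Ch")
        data.frame(complex_id = names(poses)[i],
                   residue = rep(f$residue, times = length(bits)),
                   bit = rep(bits, each = nrow(f)),
                   value = as.integer(unlist(f[bits])))
      }))
      occ <- occurrence_profile(ifps)
      p1 <- file.path(out_dir, "ifp_bits.csv")
      p2 <- file.path(out_dir, "ifp_occurrence.csv")
      utils::write.csv(long, p1, row.names = FALSE)
      utils::write.csv(occ, p2, row.names = FALSE)
      result$outputs <- c(result$outputs, p1, p2)
      list(fingerprints = ifps, occurrence = occ)
    })
  }

  if (isTRUE(cfg$stages$qsar)) {
    result$qsar <- stage("qsar", {
      if (is.null(acts)) stop("paths$activities is required for qsar")
      acts <- acts[match(names(poses), acts$id), , drop = FALSE]
      if (anyNA(acts$pKi)) stop("activities missing for some poses")
      if (all(acts$split == "unassigned")) {
        n_test <- cfg$qsar$n_test
        if (is.null(n_test)) n_test <- round(0.2 * nrow(acts))
        acts <- split_dataset(acts, n_test, seed = cfg$seed)
      }
      fm <- compute_fields(poses, spacing = cfg$fields$spacing,
                           padding = cfg$fields$padding,
                           dielectric = cfg$fields$dielectric)
      sets <- list(S = "steric", E = "electrostatic",
                   SE = c("steric", "electrostatic"))
      sets <- sets[match.arg(as.character(cfg$qsar$field_sets),
                             names(sets), several.ok = TRUE)]
      tr <- which(acts$split == "train"); te <- which(acts$split == "test")
      sel <- select_model(fm, acts$pKi[tr], rows = tr, field_sets = sets,
                          ncomp_max = cfg$qsar$ncomp_max,
                          srd = isTRUE(cfg$qsar$srd),
                          cap = cfg$pretreat$cap,
                          zero_threshold = cfg$pretreat$zero_threshold,
                          nlevel_max = cfg$pretreat$nlevel_max)
      model <- sel$model
      pred <- numeric(nrow(acts))
      pred[tr] <- model$fitted
      ext <- NULL
      if (length(te)) {
        pred[te] <- predict(model, fm, rows = te)
        if (length(te) >= 2L)
          ext <- external_stats(acts$pKi[te], pred[te])
      }
      preds <- data.frame(id = acts$id, pKi_exp = acts$pKi,
                          pKi_pred = round(pred, 4), split = acts$split)
      p1 <- file.path(out_dir, "predictions.csv")
      utils::write.csv(preds, p1, row.names = FALSE)
      contrib <- field_contributions(model)
      report <- list(fields = model$fields, ncomp = model$ncomp,
                     r2 = model$r2, s = model$s,
                     q2 = sel$q2, s_loo = sel$s_loo,
                     rtest2 = if (!is.null(ext)) ext[["rtest2"]],
                     s_test = if (!is.null(ext)) ext[["s_test"]],
                     contributions = as.list(contrib),
                     scan = sel$scan)
      p2 <- file.path(out_dir, "model.json")
      jsonlite::write_json(report, p2, auto_unbox = TRUE, digits = 10,
                           dataframe = "rows")
      cont <- export_contours(model, file.path(out_dir, "contours"),
                              percentile = cfg$contours$percentile)
      result$outputs <- c(result$outputs, p1, p2,
                           vapply(cont, function(z) z$path, ""))
      list(model = model, report = report, predictions = preds)
    })
  }

  writeLines(c(log_lines, "status: ok",
               paste("outputs:", paste(result$outputs, collapse = ", "))),
             log_path)
  invisible(result)
}

#' Summary statistics from a predictions table
#'
#' Computes the headline model statistics directly from a predictions
#' table with split flags: training `R2 = 1 - SSres/SStot`, and external
#' `Rtest2` / `S_test` as in [external_stats()].  Works on the packaged
#' activity fixture as well as on pipeline output.
#'
#' @param predictions A `data.frame` with columns `pKi_exp`, `pKi_pred`
#'   and `split`, or the path of such a CSV.
#' @return Named vector `c(r2_train = , rtest2 = , s_test = )`.
#' @export
report_split_stats <- function(predictions) {
  if (is.character(predictions))
    predictions <- utils::read.csv(predictions, stringsAsFactors = FALSE)
  need <- c("pKi_exp", "pKi_pred", "split")
  if (!all(need %in% names(predictions)))
    stop("predictions need columns: ", paste(need, collapse = ", "))
  tr <- predictions[predictions$split == "train", ]
  te <- predictions[predictions$split == "test", ]
  if (!nrow(tr) || !nrow(te)) stop("both train and test rows are required")
  r2 <- 1 - sum((tr$pKi_exp - tr$pKi_pred)^2) /
    sum((tr$pKi_exp - mean(tr$pKi_exp))^2)
  ext <- external_stats(te$pKi_exp, te$pKi_pred)
  c(r2_train = r2, rtest2 = ext[["rtest2"]], s_test = ext[["s_test"]])
}
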