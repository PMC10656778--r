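# Orchestrates the full workflow: (simulate) -> screen -> efficiency ->
# stability on all samples and on condition subsets -> consensus ->
# normalization, with a run manifest. Stages whose inputs are absent are
# skipped with a log line; a failing stage aborts the run with its name, and
# any half-written output of that stage is retained with a ".partial"
# suffix. All logging goes to stderr via message(); CSV outputs are never
# interleaved with logs.

pipeline_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

# Write a CSV atomically: the final path appears only on success.
stage_csv <- function(df, path, digits = 4) {
  tmp <- paste0(path, ".partial")
  write_report_csv(df, tmp, digits = digits)
  file.rename(tmp, path)
  nrow(df)
}

stage_matrix_csv <- function(x, path) {
  tmp <- paste0(path, ".partial")
  write_matrix_table(x, tmp)
  file.rename(tmp, path)
  nrow(x)
}

run_stage <- function(manifest, name, fun) {
  result <- tryCatch(fun(), error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  manifest$stages[[name]] <- result
  manifest
}

stability_bundle <- function(ct, cfg) {
  list(delta_ct = delta_ct_stability(ct),
       bestkeeper = bestkeeper_stability(ct, variant = cfg$bestkeeper_variant),
       genorm = genorm_stability(ct, v_cutoff = cfg$v_cutoff),
       normfinder = normfinder_stability(ct, group_by = cfg$group_by))
}

subset_ct <- function(ct, groups) {
  keep <- sample_meta(ct)$group %in% groups
  if (!any(keep)) {
    stop(sprintf("no samples in group subset: %s",
                 paste(groups, collapse = ", ")), call. = FALSE)
  }
  v <- ct_values(ct)[, keep, drop = FALSE]
  ct_matrix(v, sample_meta = sample_meta(ct)[keep, , drop = FALSE])
}

#' Run the full reference-gene identification workflow
#'
#' Executes, in order: data simulation (if requested), candidate screening
#' (if an FPKM table is available), standard-curve efficiency fitting (if
#' dilution series are available), the four stability methods on the
#' replicate-collapsed Ct matrix, subset stability runs for any configured
#' group partitions, the geometric-mean consensus ranking, and target-gene
#' normalization (if targets are configured). Each stage writes CSV outputs
#' into the configured output directory; a manifest (config snapshot, input
#' digests, package version, seed, per-stage outputs with row counts,
#' timestamps) is written as `manifest.yaml`. Re-running with identical
#' inputs and seed reproduces byte-identical CSV outputs.
#'
#' Recognised configuration fields beyond the [run_config()] defaults:
#' `simulate` (logical or a list of [sim_spec()] / [simulate_fpkm()]
#' settings), `fpkm_path`, `ct_path` + `meta_path`, `dilution_paths`,
#' `delimiter`, `include_groups` (named list of group-label subsets, each
#' re-run and aggregated separately), and `targets`, `refs`, `bad_ref`,
#' `control_group` for the normalization stage.
#'
#' @param config A `run_config` list or the path to a YAML config file.
#' @return The run manifest, invisibly (also written to `manifest.yaml`).
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) read_run_config(config) else
    validate_run_config(unclass(config))
  out <- cfg$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  delim <- if (is.null(cfg$delimiter)) "," else cfg$delimiter

  manifest <- list(package_version = as.character(utils::packageVersion("refstab")),
                   seed = cfg$seed,
                   started = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                   config = unclass(cfg), input_digests = list(),
                   stages = list())

  # ---- simulate ------------------------------------------------------------
  if (isTRUE(cfg$simulate) || is.list(cfg$simulate)) {
    manifest <- run_stage(manifest, "simulate", function() {
      sim <- if (is.list(cfg$simulate)) cfg$simulate else list()
      n_genes <- sim$n_genes %||% 29L
      n_groups <- sim$n_groups %||% 14L
      n_bio_reps <- sim$n_bio_reps %||% 3L
      tau <- sim$tau %||% seq(0.05, 1.5, length.out = n_genes)
      mu <- sim$mu %||% with_seed(cfg$seed, stats::runif(n_genes, 18, 30))
      spec <- sim_spec(mu = mu, tau = tau, n_groups = n_groups,
                       n_bio_reps = n_bio_reps,
                       loading_sd = sim$loading_sd %||% 1,
                       noise_sd = sim$noise_sd %||% 0.2, seed = cfg$seed)
      sim_ct <- simulate_ct(spec)
      fp <- simulate_fpkm(sim$fpkm_genes %||% 500L,
                          sim$fpkm_samples %||% 42L,
                          sim$fpkm_stable %||% 30L, seed = cfg$seed)
      eff <- sim$efficiencies %||% c(94.08, 100, 104.87)
      dil_paths <- character(0)
      for (i in seq_along(eff)) {
        g <- spec$gene_ids[i]
        d <- simulate_dilution(g, eff[i], noise_sd = 0.1,
                               seed = cfg$seed + i)
        p <- file.path(out, sprintf("dilution_%s.csv", g))
        stage_csv(d$points, p, digits = 6)
        dil_paths <- c(dil_paths, p)
      }
      rows_ct <- stage_matrix_csv(sim_ct$ct, file.path(out, "ct.csv"))
      write_sample_meta(sim_ct$ct, file.path(out, "meta.csv"))
      stage_csv(sim_ct$truth, file.path(out, "truth.csv"))
      stage_matrix_csv(fp$fpkm, file.path(out, "fpkm.csv"))
      cfg$ct_path <<- file.path(out, "ct.csv")
      cfg$meta_path <<- file.path(out, "meta.csv")
      cfg$fpkm_path <<- file.path(out, "fpkm.csv")
      cfg$dilution_paths <<- dil_paths
      pipeline_log("simulate", "wrote ct/meta/truth/fpkm and %d dilution series",
                   length(dil_paths))
      list(outputs = c("ct.csv", "meta.csv", "truth.csv", "fpkm.csv",
                       basename(dil_paths)), rows = rows_ct)
    })
  }

  for (p in c(cfg$fpkm_path, cfg$ct_path, cfg$meta_path, cfg$dilution_paths)) {
    if (!is.null(p) && file.exists(p)) {
      manifest$input_digests[[basename(p)]] <- unname(tools::md5sum(p))
    }
  }

  # ---- screening -----------------------------------------------------------
  if (!is.null(cfg$fpkm_path) && file.exists(cfg$fpkm_path)) {
    manifest <- run_stage(manifest, "screen", function() {
      expr <- read_expression_table(cfg$fpkm_path, delimiter = delim)
      stats_tbl <- screen_candidates(expr, mv_min = cfg$mv_min,
                                     top_n_sd = cfg$top_n_sd,
                                     cv_max = cfg$cv_max,
                                     mfc_max = cfg$mfc_max)
      n <- stage_csv(stats_tbl, file.path(out, "screening.csv"))
      pipeline_log("screen", "%d/%d genes pass the screen",
                   sum(stats_tbl$passes), n)
      list(outputs = "screening.csv", rows = n)
    })
  } else {
    pipeline_log("screen", "no FPKM table; stage skipped")
  }

  # ---- efficiency ----------------------------------------------------------
  dil <- cfg$dilution_paths
  dil <- if (is.null(dil)) character(0) else dil[file.exists(dil)]
  if (length(dil) > 0L) {
    manifest <- run_stage(manifest, "efficiency", function() {
      fits <- lapply(dil, function(p) {
        pts <- utils::read.csv(p)
        gene <- sub("^dilution_", "", sub("\\.csv$", "", basename(p)))
        fit_standard_curve(dilution_series(gene, pts$log10_amount, pts$ct))
      })
      tbl <- curve_fit_table(fits)
      n <- stage_csv(tbl, file.path(out, "curves.csv"))
      pipeline_log("efficiency", "fitted %d standard curves", n)
      list(outputs = "curves.csv", rows = n)
    })
  } else {
    pipeline_log("efficiency", "no dilution series; stage skipped")
  }

  # ---- stability + consensus ----------------------------------------------
  have_ct <- !is.null(cfg$ct_path) && file.exists(cfg$ct_path) &&
    !is.null(cfg$meta_path) && file.exists(cfg$meta_path)
  ct <- NULL
  if (have_ct) {
    ct <- collapse_technical_replicates(
      read_ct_table(cfg$ct_path, cfg$meta_path, delimiter = delim))
    manifest <- run_stage(manifest, "stability", function() {
      bundle <- stability_bundle(ct, cfg)
      outputs <- character(0)
      for (m in names(bundle)) {
        t <- if (m == "genorm") bundle[[m]]$table else bundle[[m]]
        f <- sprintf("stability_%s.csv", m)
        stage_csv(as.data.frame(t), file.path(out, f))
        outputs <- c(outputs, f)
      }
      stage_csv(bundle$genorm$pairwise_variation,
                file.path(out, "genorm_pairwise_variation.csv"))
      outputs <- c(outputs, "genorm_pairwise_variation.csv")
      cons <- aggregate_ranks(bundle)
      n <- stage_csv(as.data.frame(cons), file.path(out, "consensus.csv"))
      pipeline_log("stability", "consensus over %d genes; most stable: %s",
                   n, cons$gene_id[1L])
      list(outputs = c(outputs, "consensus.csv"), rows = n)
    })

    if (!is.null(cfg$include_groups)) {
      manifest <- run_stage(manifest, "subsets", function() {
        outputs <- character(0)
        for (nm in names(cfg$include_groups)) {
          sub <- subset_ct(ct, cfg$include_groups[[nm]])
          cons <- aggregate_ranks(stability_bundle(sub, cfg))
          f <- sprintf("consensus_%s.csv", nm)
          stage_csv(as.data.frame(cons), file.path(out, f))
          outputs <- c(outputs, f)
          pipeline_log("subsets", "%s: most stable %s", nm, cons$gene_id[1L])
        }
        list(outputs = outputs, rows = length(outputs))
      })
    }
  } else {
    pipeline_log("stability", "no Ct table; stage skipped")
  }

  # ---- normalization -------------------------------------------------------
  if (have_ct && !is.null(cfg$targets) && !is.null(cfg$refs) &&
      !is.null(cfg$control_group)) {
    manifest <- run_stage(manifest, "normalize", function() {
      prof <- expression_profile(ct, targets = cfg$targets,
                                 stable_refs = cfg$refs,
                                 unstable_ref = cfg$bad_ref %||% cfg$refs[1L],
                                 control_group = cfg$control_group)
      n <- stage_csv(prof, file.path(out, "expression.csv"))
      pipeline_log("normalize", "profiled %d target(s) over %d rows",
                   length(cfg$targets), n)
      list(outputs = "expression.csv", rows = n)
    })
  } else {
    pipeline_log("normalize", "no targets configured; stage skipped")
  }

  manifest$finished <- format(Sys.time(), "%Y-%m-%d %H:%M:%S")
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
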