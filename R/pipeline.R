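# End-to-end orchestration: structure -> one-IR removal -> diversity scan ->
# barcode mining -> discrimination, with a machine-readable report.

#' Build a run configuration
#'
#' All stage parameters default to the conventional values for plastome
#' barcode mining: 800-bp windows at a 200-bp step for the diversity scan,
#' cores no longer than 800 bp, a strict >50% bootstrap-support success rule.
#' Every parameter is echoed into the report.
#'
#' @param aln Path to an aligned FASTA (the alignment is consumed, not
#'   produced), or an alignment matrix.
#' @param groups Path to a groups TSV, or a group table data.frame.
#' @param genomes Optional path to a genomes FASTA (or list of
#'   [circular_genome()]) for the structure stage.
#' @param window,step Diversity-scan window and step (bp).
#' @param max_len,flank_len,min_diag_per_group,min_variable,max_gap_frac,
#'   scan_step,pi_cap,top Mining parameters, see [scan_candidates()].
#' @param min_ir,max_ir_mismatch Structure-stage parameters.
#' @param model,B,threshold Discrimination parameters.
#' @param seed Integer seed (bootstrap).
#' @param out_dir Optional output directory for the JSON report and TSVs.
#' @return List of class `run_config`.
#' @export
run_config <- function(aln, groups, genomes = NULL,
                       window = 800L, step = 200L,
                       max_len = 800L, flank_len = 25L,
                       min_diag_per_group = 1L, min_variable = 3L,
                       max_gap_frac = 0.05, scan_step = 50L, pi_cap = 0.05,
                       top = 5L, min_ir = 1000L, max_ir_mismatch = 0L,
                       model = "JC69", B = 1000L, threshold = 50,
                       seed = 1L, out_dir = NULL) {
  if (window < step) stop("window must be >= step", call. = FALSE)
  if (max_len < 1L || flank_len < 1L) stop("invalid mining parameters",
                                           call. = FALSE)
  structure(as.list(environment()), class = "run_config")
}

#' Run the full pipeline
#'
#' Stages, in order: per-genome quadripartite structure (when genomes are
#' given), sliding-window nucleotide diversity, diagnostic-site scan,
#' barcode-candidate mining, and per-candidate discrimination testing. Any
#' stage failure aborts with a stage-tagged error. The report is regenerable
#' byte-identically from the same inputs, configuration and seed.
#'
#' @param config A [run_config()].
#' @return List of class `run_report` with per-stage summaries.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  aln <- stage("input", {
    if (is.matrix(cfg$aln)) cfg$aln else read_alignment(cfg$aln)
  })
  groups <- stage("input", {
    g <- if (is.data.frame(cfg$groups)) cfg$groups else read_groups(cfg$groups)
    match_groups(aln, g)
  })

  structure_tab <- NULL
  if (!is.null(cfg$genomes)) {
    structure_tab <- stage("structure", {
      gs <- if (is.list(cfg$genomes) &&
                all(vapply(cfg$genomes, inherits, logical(1),
                           "circular_genome"))) {
        cfg$genomes
      } else read_genomes(cfg$genomes)
      plastome_structure(gs, min_len = cfg$min_ir,
                         max_mismatch = cfg$max_ir_mismatch)$table
    })
  }

  track <- stage("scan", {
    sliding_window_diversity(aln[!groups$outgroup, , drop = FALSE],
                             window_len = cfg$window, step = cfg$step)
  })
  diagnostic <- stage("scan", find_diagnostic_sites(aln, groups))
  site_summary <- stage("scan", count_site_classes(aln))

  candidates <- stage("mine", {
    scan_candidates(aln, groups, max_len = cfg$max_len,
                    flank_len = cfg$flank_len,
                    min_diag_per_group = cfg$min_diag_per_group,
                    min_variable = cfg$min_variable,
                    max_gap_frac = cfg$max_gap_frac, step = cfg$scan_step,
                    pi_cap = cfg$pi_cap, top = cfg$top)
  })

  discrimination <- stage("discriminate", {
    out <- list()
    for (i in seq_len(nrow(candidates))) {
      reg <- extract_region(aln, c(candidates$start[i], candidates$end[i]))
      nm <- sprintf("cand_%d_%d", candidates$start[i], candidates$end[i])
      res <- evaluate_discrimination(reg, groups, model = cfg$model,
                                     B = cfg$B, seed = cfg$seed,
                                     threshold = cfg$threshold)
      # region site classes, Table-3 style
      out[[nm]] <- list(region = c(candidates$start[i], candidates$end[i]),
                        sites = count_site_classes(reg),
                        result = res)
    }
    out
  })

  report <- structure(list(
    config = cfg[setdiff(names(cfg), c("aln", "groups", "genomes",
                                       "out_dir"))],
    n_samples = nrow(aln), n_columns = ncol(aln),
    structure = structure_tab,
    diversity = track,
    site_summary = site_summary,
    n_diagnostic_sites = nrow(diagnostic),
    diagnostic_sites = diagnostic,
    candidates = candidates,
    discrimination = discrimination
  ), class = "run_report")

  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  alignment: %d samples x %d columns\n", x$n_samples,
              x$n_columns))
  if (!is.null(x$structure)) {
    cat(sprintf("  structure: %d genomes partitioned\n",
                sum(!is.na(x$structure$ir))))
  }
  cat(sprintf("  diversity: %d windows, max pi %.4g\n", nrow(x$diversity),
              max(x$diversity$pi, na.rm = TRUE)))
  cat(sprintf("  diagnostic sites: %d; candidates: %d\n",
              x$n_diagnostic_sites, nrow(x$candidates)))
  for (nm in names(x$discrimination)) {
    res <- x$discrimination[[nm]]$result
    cat(sprintf("  %s: %d/%d groups discriminated\n", nm,
                sum(res$success, na.rm = TRUE), sum(!is.na(res$success))))
  }
  invisible(x)
}

#' Write a run report as JSON and TSVs
#'
#' @param report A `run_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(report$structure)) wt(report$structure, "structure.tsv")
  wt(as.data.frame(report$diversity), "diversity.tsv")
  wt(report$diagnostic_sites, "diagnostic_sites.tsv")
  wt(as.data.frame(report$candidates), "candidates.tsv")
  disc <- lapply(names(report$discrimination), function(nm) {
    d <- report$discrimination[[nm]]$result
    cbind(region = nm, as.data.frame(d))
  })
  if (length(disc) > 0L) wt(do.call(rbind, disc), "discrimination.tsv")

  json <- list(
    config = report$config,
    n_samples = report$n_samples, n_columns = report$n_columns,
    structure = report$structure,
    diversity = as.data.frame(report$diversity),
    site_summary = unclass(report$site_summary),
    n_diagnostic_sites = report$n_diagnostic_sites,
    candidates = as.data.frame(report$candidates),
    discrimination = lapply(report$discrimination, function(d) {
      list(region = d$region, sites = unclass(d$sites),
           result = as.data.frame(d$result))
    }))
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Check a serialized report against the shipped schema
#'
#' Structural check of `report.json` against the JSON schema published with
#' the package (`inst/schema/run_report.schema.json`): all required top-level
#' keys and required per-record fields must be present.
#'
#' @param path Path to a `report.json` written by [write_report()].
#' @return `TRUE` invisibly, or an error naming the missing keys.
#' @export
validate_report_json <- function(path) {
  js <- jsonlite::read_json(path)
  schema <- jsonlite::read_json(system.file("schema",
                                            "run_report.schema.json",
                                            package = "plastidscan"))
  need <- unlist(schema$required)
  miss <- setdiff(need, names(js))
  if (length(miss) > 0L) {
    stop("report is missing required keys: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  cfg_need <- unlist(schema$properties$config$required)
  miss <- setdiff(cfg_need, names(js$config))
  if (length(miss) > 0L) {
    stop("report config is missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  div_need <- unlist(schema$properties$diversity$items$required)
  if (length(js$diversity) > 0L) {
    miss <- setdiff(div_need, names(js$diversity[[1L]]))
    if (length(miss) > 0L) {
      stop("diversity records are missing: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Compare two barcode panels
#'
#' Per-panel totals (length, variable sites, parsimony-informative sites,
#' groups successfully discriminated on the concatenated panel) and their
#' differences.
#'
#' @param aln Alignment matrix.
#' @param groups Group table.
#' @param panel_a,panel_b Named lists of `c(start, end)` spans.
#' @param model,B,seed,threshold Discrimination settings.
#' @return data.frame with rows `panel_a`, `panel_b`, `delta`.
#' @export
compare_barcode_panels <- function(aln, groups, panel_a, panel_b,
                                   model = "JC69", B = 200L, seed = 1L,
                                   threshold = 50) {
  if (length(panel_a) == 0L || length(panel_b) == 0L) {
    stop("empty barcode panel", call. = FALSE)
  }
  eval_panel <- function(panel) {
    parts <- lapply(panel, function(sp) {
      if (sp[2L] > ncol(aln)) stop("unknown region: span outside alignment",
                                   call. = FALSE)
      extract_region(aln, sp)
    })
    cat_aln <- concatenate_regions(parts)
    sc <- count_site_classes(cat_aln)
    disc <- evaluate_discrimination(cat_aln, groups, model = model, B = B,
                                    seed = seed, threshold = threshold)
    c(length = ncol(cat_aln), variable = sc$n_variable,
      parsimony_informative = sc$n_parsimony_informative,
      groups_discriminated = sum(disc$success, na.rm = TRUE))
  }
  a <- eval_panel(panel_a); b <- eval_panel(panel_b)
  out <- rbind(panel_a = a, panel_b = b, delta = a - b)
  as.data.frame(out)
}
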