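#' Read a pipeline configuration from YAML
#'
#' The configuration is a plain list: input paths (`genome`, `coords`,
#' `cds`, `proteins`, `primers`, `training_set`, `ct_table`; every one
#' optional — stages without inputs are skipped), a `params` block, an
#' `out_dir` and a `seed`. See [runPipeline()] for the parameters.
#'
#' @param path path to a YAML file.
#' @return configuration list.
#' @export
readPipelineConfig <- function(path) yaml::read_yaml(path)

.fmt <- function(x, digits) formatC(x, format = "f", digits = digits)

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

.defaultParams <- function() {
  list(pseudocount = 0.5, background = "uniform", top_k = 3L,
       upstream_len = 200L, genome_avg_gc = 0.59, alpha = 0.01,
       reference_gene = "alaS", control_condition = "control_30C",
       expression_alpha = 0.05, fc_floor = 2.0)
}

#' Run the full sHSP analysis pipeline
#'
#' Orchestrates the stages on whichever inputs the configuration
#' provides: upstream extraction (genome + coordinates), promoter
#' scanning (training set + upstream windows), in-silico PCR (primers +
#' genome or CDS templates), GC-composition screening (CDS), protein
#' characterisation (proteins), and relative expression (Ct table).
#' Each stage writes a fixed-format TSV into `out_dir` and one log line
#' into `run_log.txt`; reported GC percentages and pI values are
#' printed to 2 decimals and molecular weights to the nearest Da.
#' Outputs are deterministic: identical configuration and seed give
#' byte-identical files.
#'
#' @param config list (or path to a YAML file, read with
#'   [readPipelineConfig()]) with input paths, `params`, `out_dir`,
#'   `seed`.
#' @param out_dir overrides `config$out_dir`.
#' @return invisibly, a list of the per-stage data frames and the
#'   output paths.
#' @export
runPipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- readPipelineConfig(config)
  params <- utils::modifyList(.defaultParams(),
                              if (is.null(config$params)) list()
                              else config$params)
  out_dir <- if (!is.null(out_dir)) out_dir else config$out_dir
  if (is.null(out_dir)) stop("an output directory is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logLines <- c(
    sprintf("sHSPpipe %s", as.character(utils::packageVersion("sHSPpipe"))),
    sprintf("seed: %s", if (is.null(config$seed)) "none" else config$seed),
    sprintf("params: %s", paste(names(params), unlist(params),
                                sep = "=", collapse = " "))
  )
  results <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  background <- if (identical(params$background, "uniform"))
    uniformBackground()
  else gcBackground(as.numeric(sub("^gc:", "", params$background)))

  windows <- NULL
  if (!is.null(config$genome) && !is.null(config$coords)) {
    stage("upstream_extraction", {
      genome <- readSequences(config$genome, "dna")
      coords <- readCoordinates(config$coords)
      windows <- stats::setNames(lapply(seq_len(nrow(coords)), function(i) {
        g <- genome[[match(coords$replicon[i], names(genome))]]
        extractUpstream(g, coords[i, ], params$upstream_len)
      }), coords$locus)
      windows <- vapply(windows, as.character, character(1))
      writeSequences(windows, file.path(out_dir, "upstream.fa"))
      logLines <- c(logLines, sprintf(
        "upstream_extraction: %d windows of up to %d nt",
        length(windows), params$upstream_len))
    })
  } else if (!is.null(config$upstream)) {
    windows <- as.character(readSequences(config$upstream, "dna"))
  }

  if (!is.null(config$training_set) && !is.null(windows)) {
    stage("promoter_scan", {
      ts <- readTrainingSet(config$training_set)
      model <- fitSigma32Model(ts, params$pseudocount, background)
      rep <- reportPromoters(model, windows, params$top_k)
      num <- vapply(rep, is.numeric, logical(1)) &
        !(names(rep) %in% c("pos35", "pos10", "spacer_len",
                            "dist_to_start", "offset_from_ATG"))
      rep[num] <- lapply(rep[num], .fmt, digits = 3)
      results$promoters <- rep
      .writeTsv(rep, file.path(out_dir, "promoters.tsv"))
      logLines <- c(logLines, sprintf(
        "promoter_scan: %d training sites, spacer %d-%d, Rsequence %.3f bits, %d rows",
        nrow(ts), spacerRange(model)[1], spacerRange(model)[2],
        informationContent(pwm35(model)) + informationContent(pwm10(model)),
        nrow(rep)))
    })
  }

  if (!is.null(config$cds)) {
    stage("composition", {
      cds <- readSequences(config$cds, "dna")
      comp <- as.data.frame(hgtScreen(cds, params$genome_avg_gc,
                                      params$alpha))
      comp$gc_percent <- .fmt(comp$gc_percent, 2)
      comp$chi_square <- .fmt(comp$chi_square, 4)
      comp$p_value <- formatC(comp$p_value, format = "g", digits = 4)
      results$composition <- comp
      .writeTsv(comp, file.path(out_dir, "composition.tsv"))
      logLines <- c(logLines, sprintf(
        "composition: %d CDSs vs background GC %.2f, alpha %.2g",
        nrow(comp), params$genome_avg_gc, params$alpha))
    })
  }

  if (!is.null(config$proteins)) {
    stage("protein_props", {
      prot <- readSequences(config$proteins, "protein")
      props <- as.data.frame(proteinProperties(prot))
      props$mw_da <- as.integer(round(props$mw_da))
      props$pi <- .fmt(props$pi, 2)
      results$protein_props <- props
      .writeTsv(props, file.path(out_dir, "protein_props.tsv"))
      if (length(prot) >= 2L) {
        sim <- proteinSimilarityTable(prot)
        sim$identity_pct <- as.integer(round(sim$identity_pct))
        sim$similarity_pct <- as.integer(round(sim$similarity_pct))
        results$protein_similarity <- sim
        .writeTsv(sim, file.path(out_dir, "protein_similarity.tsv"))
      }
      logLines <- c(logLines,
                     sprintf("protein_props: %d proteins", nrow(props)))
    })
  }

  if (!is.null(config$primers)) {
    stage("insilico_pcr", {
      primers <- readPrimerTable(config$primers)
      tplPath <- if (!is.null(config$genome)) config$genome else config$cds
      if (is.null(tplPath))
        stop("in-silico PCR needs a genome or CDS FASTA as template")
      tpl <- readSequences(tplPath, "dna")
      pcr <- do.call(rbind, lapply(seq_len(nrow(primers)), function(i) {
        amp <- tryCatch(
          max(vapply(as.character(tpl), function(t)
            as.integer(findAmplicon(t, primers$forward[i],
                                    primers$reverse[i])),
            integer(1)), na.rm = TRUE),
          warning = function(w) NA_integer_)
        data.frame(gene = primers$gene[i],
                   amplicon_bp = if (is.finite(amp)) amp else NA_integer_)
      }))
      if ("expected_amplicon_bp" %in% names(primers))
        pcr$expected_amplicon_bp <- primers$expected_amplicon_bp
      results$pcr <- pcr
      .writeTsv(pcr, file.path(out_dir, "pcr.tsv"))
      logLines <- c(logLines,
                     sprintf("insilico_pcr: %d primer pairs", nrow(pcr)))
    })
  }

  if (!is.null(config$ct_table)) {
    stage("expression", {
      ct <- readCtTable(config$ct_table)
      expr <- relativeExpressionTable(
        ct, params$reference_gene, params$control_condition,
        alpha = params$expression_alpha, fcFloor = params$fc_floor)
      num <- vapply(expr, is.numeric, logical(1))
      expr[num] <- lapply(expr[num], .fmt, digits = 4)
      results$expression <- expr
      .writeTsv(expr, file.path(out_dir, "expression.tsv"))
      logLines <- c(logLines,
                     sprintf("expression: %d gene/condition results",
                             nrow(expr)))
    })
  } else {
    logLines <- c(logLines, "expression: skipped (no Ct table)")
  }

  writeLines(logLines, file.path(out_dir, "run_log.txt"))
  invisible(c(results, list(out_dir = out_dir, log = logLines)))
}
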