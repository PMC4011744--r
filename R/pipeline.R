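#' Run the full co-occurrence analysis workflow from a config
#'
#' Executes the selected stages in analysis order — simulate (or load),
#' prepare (filters + binarize), diversity, compare, pairs, hostdiff,
#' community — writing one TSV per analysis and a JSON run manifest with
#' the config snapshot, seeds, input/output hashes and per-stage timings.
#' Reruns with an identical config produce byte-identical outputs.
#'
#' @param config Path to a YAML config file, or an equivalent named list.
#'   Recognized top-level keys: `seed`; `simulate` (a [sim_config()]
#'   argument list, or `true` for defaults); `input` (list with `counts`,
#'   optional `metadata`, `orientation`); `prepare` (`min_reads`,
#'   `threshold`); `stages` (character vector among `diversity`,
#'   `compare`, `pairs`, `hostdiff`, `community`); `pairs`
#'   (`min_occurrence`, `min_pair_sum`, `randomizations`, `null_model`,
#'   `normalize`); `hostdiff` (`min_occurrence`, `min_pair_sum`,
#'   `randomizations`); `community` (`randomizations`, `subsets`: named
#'   lists of OTU ids); `diversity` (`raup_crick_reps`,
#'   `mantel_class_width`, `morans_min_occurrence`, `permutations`).
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly (also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1
  stages <- config$stages %||%
    c("diversity", "compare", "pairs", "hostdiff", "community")
  manifest <- list(config = config, seed = seed, outputs = list(),
                   timings = list())
  t_all <- proc.time()[3]

  stage <- function(name, fn) {
    t0 <- proc.time()[3]
    res <- tryCatch(fn(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    manifest$timings[[name]] <<- round(proc.time()[3] - t0, 3)
    res
  }
  emit <- function(df, file) {
    path <- file.path(out_dir, file)
    utils::write.table(df, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    manifest$outputs[[file]] <<- unname(tools::md5sum(path))
    path
  }

  # --- input or simulation -------------------------------------------
  if (!is.null(config$simulate)) {
    sim <- stage("simulate", function() {
      args <- if (isTRUE(config$simulate)) list() else config$simulate
      args$seed <- args$seed %||% seed
      if (!is.null(args$couplings))
        args$couplings <- as.data.frame(lapply(args$couplings, unlist))
      simulate_community(do.call(sim_config, args))
    })
    table <- sim$table
    metadata <- sim$metadata
    emit(data.frame(sample_id = rownames(table), unclass(table),
                    check.names = FALSE), "simulated_counts.tsv")
    emit(metadata, "simulated_metadata.tsv")
    if (nrow(sim$truth$couplings) > 0)
      emit(sim$truth$couplings, "simulated_truth.tsv")
  } else if (!is.null(config$input)) {
    table <- read_count_table(config$input$counts,
                              config$input$orientation %||%
                                "samples_by_otus")
    metadata <- if (!is.null(config$input$metadata))
      utils::read.table(config$input$metadata, header = TRUE, sep = ",",
                        stringsAsFactors = FALSE)
    else NULL
  } else stop("config needs either 'simulate' or 'input'")
  if (is.null(metadata))
    metadata <- data.frame(sample_id = rownames(table), host = "all",
                           exclude_flag = FALSE)

  # --- prepare -------------------------------------------------------
  prep <- config$prepare %||% list()
  mat <- stage("prepare", function()
    prepare_matrix(table, metadata,
                   min_reads = prep$min_reads %||% 20,
                   threshold = prep$threshold %||% 0.05))
  metadata <- metadata[match(rownames(mat), metadata$sample_id), ]
  emit(data.frame(sample_id = rownames(mat), unclass(mat),
                  check.names = FALSE), "binary_matrix.tsv")
  hosts <- metadata$host
  two_hosts <- length(unique(hosts)) == 2
  dv <- config$diversity %||% list()
  d_rc <- NULL
  get_rc <- function() {
    if (is.null(d_rc))
      d_rc <<- raup_crick(mat, reps = dv$raup_crick_reps %||% 999,
                          seed = child_seed(seed, 11))
    d_rc
  }

  # --- diversity -----------------------------------------------------
  if ("diversity" %in% stages) {
    stage("diversity", function() {
      emit(mao_tau(mat), "accumulation.tsv")
      d <- get_rc()
      if (all(c("x", "y") %in% names(metadata))) {
        coords <- metadata[, c("x", "y")]
        emit(mantel_correlogram(d, coords,
                                class_width = dv$mantel_class_width %||% 2,
                                permutations = dv$permutations %||% 999,
                                seed = child_seed(seed, 12)),
             "mantel_correlogram.tsv")
        min_occ <- dv$morans_min_occurrence %||% 10
        common <- which(occurrence(mat) >= min_occ)
        if (length(common) > 0) {
          mi <- do.call(rbind, lapply(common, function(o) {
            r <- morans_i(unclass(mat)[, o], coords)
            data.frame(otu_id = colnames(mat)[o], I = r$I,
                       expectation = r$expectation, sd = r$sd, P = r$P)
          }))
          mi$q <- bh_adjust(mi$P)
          emit(mi, "morans_i.tsv")
        }
      }
      invisible(NULL)
    })
  }

  # --- compare -------------------------------------------------------
  if ("compare" %in% stages && two_hosts) {
    stage("compare", function() {
      d_rc <- get_rc()
      pa <- permanova(d_rc, hosts,
                      permutations = dv$permutations %||% 9999,
                      seed = child_seed(seed, 21))
      pd <- permdisp(d_rc, hosts,
                     permutations = dv$permutations %||% 9999,
                     seed = child_seed(seed, 22))
      wt <- richness_welch_t(mat, hosts)
      emit(data.frame(
        method = c("permanova", "permdisp", "welch_t"),
        statistic = c(pa$F, pd$F, wt$t),
        R2_or_df = c(pa$R2, NA, wt$df),
        P = c(pa$P, pd$P, wt$P)), "comparison.tsv")
      occ1 <- colSums(unclass(mat)[hosts == sort(unique(hosts))[1], ,
                                   drop = FALSE])
      occ2 <- colSums(unclass(mat)[hosts == sort(unique(hosts))[2], ,
                                   drop = FALSE])
      emit(clam_test(occ1, occ2, colnames(mat)), "clam.tsv")
    })
  }

  # --- pair tests ----------------------------------------------------
  pr <- config$pairs %||% list()
  M <- pr$randomizations %||% 10000
  if ("pairs" %in% stages) {
    stage("pairs", function() {
      pooled <- screen_pairs(mat, pr$min_occurrence %||% 10,
                             pr$min_pair_sum %||% 50)
      if (nrow(pooled) > 0) {
        ens <- build_ensemble(mat, pr$null_model %||%
                                "fixed_fixed_curveball",
                              M = M, seed = child_seed(seed, 31))
        emit(pair_randomization_test(mat, pooled, ens,
                                     normalize = pr$normalize %||% "range"),
             "pairs_pooled.tsv")
      }
      if (two_hosts) {
        for (h in unique(hosts)) {
          sub <- as_bincom(unclass(mat)[hosts == h, , drop = FALSE])
          ph <- screen_pairs(sub, pr$host_min_occurrence %||% 5,
                             pr$host_min_pair_sum %||% 25)
          if (nrow(ph) == 0) next
          ensh <- build_ensemble(sub, M = M, seed = child_seed(seed, 32))
          emit(pair_randomization_test(sub, ph, ensh,
                                       normalize = pr$normalize %||% "range"),
               sprintf("pairs_%s.tsv", h))
        }
      }
    })
  }

  # --- host contrast -------------------------------------------------
  hd <- config$hostdiff %||% list()
  if ("hostdiff" %in% stages && two_hosts) {
    stage("hostdiff", function()
      emit(host_difference_test(mat, hosts,
                                min_occurrence = hd$min_occurrence %||% 5,
                                min_pair_sum = hd$min_pair_sum %||% 25,
                                M = hd$randomizations %||% M,
                                seed = child_seed(seed, 41)),
           "host_contrast.tsv"))
  }

  # --- community tests -----------------------------------------------
  cm <- config$community %||% list()
  if ("community" %in% stages) {
    stage("community", function() {
      ens <- build_ensemble(mat, M = cm$randomizations %||% M,
                            seed = child_seed(seed, 51))
      subsets <- c(list(All = NULL), cm$subsets %||% list())
      res <- do.call(rbind, unlist(lapply(names(subsets), function(nm) {
        lapply(c("C", "T"), function(sc)
          community_score_test(mat, subsets[[nm]], ens, score = sc,
                               label = nm))
      }), recursive = FALSE))
      emit(res, "community_tests.tsv")
    })
  }

  manifest$timings$total <- round(proc.time()[3] - t_all, 3)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
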