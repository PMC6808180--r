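#' Write a cohort to delimited text
#'
#' Writes the score matrix (one child per row, comma-separated, header row)
#' and, when supplied, the label table keyed by \code{child_id}.
#'
#' @param cohort A \code{cohort_matrix}.
#' @param scores_path Output CSV path for scores.
#' @param labels,labels_path Optional label table and its output path.
#' @return Invisibly, the score path.
#' @export
write_cohort <- function(cohort, scores_path, labels = NULL,
                         labels_path = NULL) {
  df <- data.frame(child_id = cohort$child_ids, cohort$scores,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, scores_path, row.names = FALSE)
  if (!is.null(labels) && !is.null(labels_path))
    utils::write.csv(labels, labels_path, row.names = FALSE)
  invisible(scores_path)
}

#' Read a cohort from delimited text
#'
#' Reads a score table written by \code{\link{write_cohort}} (or any CSV
#' with a \code{child_id} column and one column per measure). Children
#' missing any cognitive measure are excluded -- a message reports how many
#' -- because the map training requires complete cognitive vectors; missing
#' values on other families are kept.
#'
#' @param scores_path CSV of scores with a \code{child_id} column.
#' @param labels_path Optional CSV of labels keyed by \code{child_id}.
#' @param measures data.frame mapping measure \code{name} to \code{family};
#'   defaults to \code{\link{default_measures}}. Score columns not listed
#'   are tagged \code{behavior}.
#' @return List with \code{cohort} (a \code{cohort_matrix}),
#'   \code{labels} (or NULL), and \code{n_excluded}.
#' @export
read_cohort <- function(scores_path, labels_path = NULL,
                        measures = default_measures()) {
  if (!file.exists(scores_path)) stop("no such file: ", scores_path)
  df <- utils::read.csv(scores_path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty cohort file: ", scores_path)
  if (!"child_id" %in% names(df)) stop("scores file must have a child_id column")
  if (anyDuplicated(df$child_id))
    stop("duplicate child_id: ",
         paste(unique(df$child_id[duplicated(df$child_id)]), collapse = ", "))
  meas_cols <- setdiff(names(df), "child_id")
  fam <- measures$family[match(meas_cols, measures$name)]
  fam[is.na(fam)] <- "behavior"
  scores <- as.matrix(df[, meas_cols, drop = FALSE])
  if (!is.numeric(scores)) {
    bad <- which(!vapply(df[meas_cols], is.numeric, logical(1)))
    stop("non-numeric measure column(s): ",
         paste(meas_cols[bad], collapse = ", "))
  }
  complete_cog <- stats::complete.cases(scores[, fam == "cognitive",
                                               drop = FALSE])
  n_excl <- sum(!complete_cog)
  if (n_excl > 0)
    message(n_excl, " of ", nrow(df),
            " children excluded for missing cognitive data; ",
            sum(complete_cog), " included")
  cohort <- cohort_matrix(scores[complete_cog, , drop = FALSE],
                          df$child_id[complete_cog], fam)
  labels <- NULL
  if (!is.null(labels_path)) {
    labels <- utils::read.csv(labels_path, stringsAsFactors = FALSE)
    labels <- labels[match(cohort$child_ids, labels$child_id), , drop = FALSE]
    rownames(labels) <- NULL
  }
  list(cohort = cohort, labels = labels, n_excluded = n_excl)
}

#' Write connectomes as per-child matrix files
#'
#' One whitespace-delimited square matrix file per child (filename =
#' child id) plus a two-column ROI-to-lobe map file.
#'
#' @param connectomes Named list of ROI x ROI matrices.
#' @param dir Output directory (created if needed).
#' @param lobe_map Optional character vector of lobe labels per ROI.
#' @return Invisibly, the directory.
#' @export
write_connectomes <- function(connectomes, dir, lobe_map = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(names(connectomes)))
    names(connectomes) <- sprintf("child_%04d", seq_along(connectomes))
  for (id in names(connectomes))
    utils::write.table(connectomes[[id]], file.path(dir, paste0(id, ".txt")),
                       row.names = FALSE, col.names = FALSE)
  if (!is.null(lobe_map))
    utils::write.table(
      data.frame(roi = seq_along(lobe_map), lobe = lobe_map),
      file.path(dir, "lobe_map.txt"), row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read connectomes written by \code{write_connectomes}
#'
#' @param dir Directory of per-child matrix files.
#' @return Named list of matrices (lobe map, if present, attached as the
#'   \code{lobe_map} attribute).
#' @export
read_connectomes <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  files <- files[basename(files) != "lobe_map.txt"]
  out <- lapply(files, function(f) as.matrix(utils::read.table(f)))
  out <- lapply(out, unname)
  names(out) <- sub("\\.txt$", "", basename(files))
  lm_path <- file.path(dir, "lobe_map.txt")
  if (file.exists(lm_path))
    attr(out, "lobe_map") <- utils::read.table(lm_path, header = TRUE,
                                               stringsAsFactors = FALSE)$lobe
  out
}

#' Run the full phenotyping pipeline
#'
#' Executes, in order: synthetic cohort generation (or reading from file),
#' consensus SOM clustering, topographic category tests, cluster profile
#' statistics, and (optionally) the two-stage connectome comparison. Every
#' output table is written to \code{out_dir} as delimited text along with a
#' config echo containing the master seed and a hash of the configuration,
#' so reruns with the same config are identical.
#'
#' @param config A named list (or path to a YAML file) with components:
#'   \describe{
#'     \item{generator}{list of \code{\link{cohort_config}} arguments, or
#'       \code{input = list(scores, labels)} paths instead.}
#'     \item{som}{list of \code{\link{som_config}} arguments.}
#'     \item{consensus}{\code{k}, \code{n_iterations}.}
#'     \item{topo}{\code{categories}, \code{n_permutations}.}
#'     \item{connectome}{optional: \code{n_per_group}, \code{n_rois},
#'       \code{deficit_regions}, \code{deficit_delta}, \code{deficit_groups},
#'       \code{noise_sd}, \code{base_weight}.}
#'     \item{seed}{master seed (required).}
#'   }
#' @param out_dir Output directory.
#' @return Invisibly, a list with the cohort, labels, consensus result,
#'   topographic tests, profile statistics, and connectome results (NULL
#'   when disabled).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config$seed is required")
  seed <- as.integer(config$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # --- data: generate or read ---------------------------------------------
  if (!is.null(config$generator$input)) {
    inp <- config$generator$input
    rd <- read_cohort(inp$scores, inp$labels)
    cohort <- rd$cohort
    labels <- rd$labels
  } else {
    gen_args <- config$generator %||% list()
    gen_args$seed <- seed
    gc_ <- do.call(cohort_config, gen_args)
    gen <- generate_cohort(gc_)
    cohort <- gen$cohort
    labels <- gen$labels
    write_cohort(cohort, file.path(out_dir, "cohort.csv"),
                 labels, file.path(out_dir, "labels.csv"))
  }

  # --- consensus SOM clustering -------------------------------------------
  som_args <- config$som %||% list()
  scfg <- do.call(som_config, som_args)
  k <- config$consensus$k %||% 4
  n_iter <- config$consensus$n_iterations %||% 1000
  cons <- consensus(cohort, scfg, k = k, n_iterations = n_iter,
                    seed = seed + 1L)
  utils::write.csv(
    data.frame(child_id = cohort$child_ids,
               modal_cluster = cons$modal_cluster,
               consistency = cons$consistency,
               clarity_p = cons$clarity_p),
    file.path(out_dir, "consensus_children.csv"), row.names = FALSE)

  profile <- cluster_profile_table(cohort, cons$modal_cluster, labels)
  utils::write.csv(profile, file.path(out_dir, "cluster_profiles.csv"),
                   row.names = FALSE)

  # --- topographic category tests -----------------------------------------
  topo <- NULL
  if (!is.null(config$topo$categories) && !is.null(labels)) {
    topo <- topography_tests(
      cons$reference_som, labels, config$topo$categories,
      n_permutations = config$topo$n_permutations %||% 9999,
      seed = seed + 2L)
    utils::write.csv(topo, file.path(out_dir, "topo_tests.csv"),
                     row.names = FALSE)
  }

  # --- profile statistics ---------------------------------------------------
  stats_out <- compare_cluster_profiles(cohort, cons$modal_cluster)
  utils::write.csv(stats_out$tests,
                   file.path(out_dir, "group_comparisons.csv"),
                   row.names = FALSE)
  pw <- do.call(rbind, lapply(names(stats_out$pairwise), function(m)
    cbind(measure = m, stats_out$pairwise[[m]])))
  utils::write.csv(pw, file.path(out_dir, "tukey_pairwise.csv"),
                   row.names = FALSE)

  cat_tests <- NULL
  if (!is.null(labels)) {
    sizes <- tabulate(cons$modal_cluster, k)
    flag_cols <- names(labels)[vapply(labels, is.logical, logical(1))]
    cat_tests <- do.call(rbind, lapply(flag_cols, function(cc) {
      counts <- vapply(seq_len(k), function(cl)
        sum(labels[[cc]][cons$modal_cluster == cl]), integer(1))
      ct <- category_distribution_chi2(counts, sizes, cc)
      data.frame(category = cc, chi2 = ct$chi2, df = ct$df,
                 p_raw = ct$p_value, stringsAsFactors = FALSE)
    }))
    if (!is.null(cat_tests)) {
      cat_tests$p_corrected <- bonferroni_by_family(cat_tests$p_raw)
      utils::write.csv(cat_tests, file.path(out_dir, "category_tests.csv"),
                       row.names = FALSE)
    }
  }

  # --- connectome comparison (optional) -------------------------------------
  conn <- NULL
  if (!is.null(config$connectome)) {
    cc <- config$connectome
    sets <- generate_connectomes(
      n_per_group = unlist(cc$n_per_group),
      n_rois = cc$n_rois %||% 85,
      base_weight = cc$base_weight %||% 1,
      deficit_regions = cc$deficit_regions %||% integer(0),
      deficit_delta = cc$deficit_delta %||% 0,
      deficit_groups = cc$deficit_groups %||% character(0),
      noise_sd = cc$noise_sd %||% 0.1,
      seed = seed + 3L)
    strengths <- lapply(sets, regional_strength)
    groups <- names(strengths)
    if (length(groups) >= 3) {
      conn <- two_stage_region_test(strengths[[1]], strengths[[2]],
                                    strengths[[3]])
      utils::write.csv(conn, file.path(out_dir, "region_tests.csv"),
                       row.names = FALSE)
    }
  }

  # --- config echo ----------------------------------------------------------
  echo <- config
  echo$master_seed <- seed
  echo$config_hash <- sum(utf8ToInt(paste(deparse(config), collapse = "")))
  yaml::write_yaml(echo, file.path(out_dir, "config_echo.yml"))

  invisible(list(cohort = cohort, labels = labels, consensus = cons,
                 topo = topo, profile = profile, stats = stats_out,
                 category_tests = cat_tests, connectome = conn))
}
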