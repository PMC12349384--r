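default_pipeline_params <- function() {
  list(probe_coords = "bed", tss_distance = 1500, require_ndr = TRUE,
       hypometh_cutoff = NULL, meth_cutoff = NULL, min_case = NULL,
       alpha = 0.05, tf_only = TRUE, top_n_genes = 1,
       quadrant = "hypo_up", top_n = 10)
}

#' Assemble a pipeline configuration
#'
#' Either pass a YAML file with `inputs`, `params` and `out_dir` keys, or
#' build the config in code. Any parameter passed directly overrides the
#' file.
#'
#' @param file Optional YAML config path.
#' @param inputs Named list of input paths: `beta`, `expression`, `probes`,
#'   `genes`, `samples`, and one or more `enhancer_bed`, `promoter_bed`,
#'   `ndr_bed` paths (character vectors allowed — multiple files per mark
#'   class are unioned).
#' @param out_dir Output directory.
#' @param ... Stage parameters overriding the defaults: `probe_coords`
#'   ("bed"/"one-based"), `tss_distance`, `require_ndr`, `hypometh_cutoff` +
#'   `meth_cutoff` (user cutoffs; both or neither), `min_case`, `alpha`,
#'   `tf_only`, `top_n_genes` (per-probe rank cutoff; `Inf` disables rank
#'   selection), `quadrant`, `top_n`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(file = NULL, inputs = NULL, out_dir = NULL, ...) {
  cfg <- list(inputs = list(), params = default_pipeline_params(), out_dir = NULL)
  if (!is.null(file)) {
    if (!file.exists(file)) stop("config file not found: ", file, call. = FALSE)
    y <- yaml::read_yaml(file)
    cfg$inputs <- utils::modifyList(cfg$inputs, y$inputs %||% list())
    cfg$params <- utils::modifyList(cfg$params, y$params %||% list())
    cfg$out_dir <- y$out_dir %||% cfg$out_dir
  }
  if (!is.null(inputs)) cfg$inputs <- utils::modifyList(cfg$inputs, inputs)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg$params))
  if (length(bad) > 0L) stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
  cfg$params <- utils::modifyList(cfg$params, dots, keep.null = FALSE)
  required <- c("beta", "expression", "probes", "genes", "samples",
                "enhancer_bed", "promoter_bed", "ndr_bed")
  missing_in <- setdiff(required, names(cfg$inputs))
  if (length(missing_in) > 0L) {
    stop("config lacks input path(s): ", paste(missing_in, collapse = ", "), call. = FALSE)
  }
  for (f in unlist(cfg$inputs[required])) {
    if (!file.exists(f)) stop("input file does not exist: ", f, call. = FALSE)
  }
  if (is.null(cfg$out_dir)) stop("config lacks out_dir", call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

read_bed_union <- function(paths) {
  dplyr::bind_rows(lapply(paths, read_bed)) |> validate_intervals()
}

#' Run the full discovery pipeline (steps 1-6) in one call
#'
#' Chains RE annotation, methylation categorization, probe-gene linking and
#' TF ranking, writing every intermediate table plus a run manifest (JSON
#' with parameters, input checksums and package version) to `out_dir`. The
#' run is deterministic: identical inputs and config give byte-identical
#' output TSVs.
#'
#' @param config A [pipeline_config()] object (or a YAML path, which is
#'   passed through `pipeline_config(file = config)`).
#' @return Invisibly, a list with `re_annotation`, `cutoffs`, `categories`,
#'   `links`, `tf_summary`, `tf_ranking` and the output `paths`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- pipeline_config(file = config)
  stopifnot(inherits(config, "pipeline_config"))
  p <- config$params
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }

  probes <- run_stage("annotate", function() {
    read_probe_manifest(config$inputs$probes, coords = p$probe_coords)
  })
  genes <- read_gene_annotation(config$inputs$genes)
  samples <- read_sample_table(config$inputs$samples)
  beta <- read_matrix(config$inputs$beta, "beta")
  expr <- read_matrix(config$inputs$expression, "expression")

  re_ann <- run_stage("annotate", function() {
    classify_re_probes(probes,
                       enhancer_marks = read_bed_union(config$inputs$enhancer_bed),
                       promoter_marks = read_bed_union(config$inputs$promoter_bed),
                       ndr = read_bed_union(config$inputs$ndr_bed),
                       genes = genes, tss_distance = p$tss_distance,
                       require_ndr = p$require_ndr)
  })
  re_probes <- re_ann$probe_id[re_ann$re_class != "none"]
  beta_re <- beta[intersect(rownames(beta), re_probes), , drop = FALSE]

  cutoffs <- run_stage("classify", function() {
    if (!is.null(p$hypometh_cutoff) || !is.null(p$meth_cutoff)) {
      if (is.null(p$hypometh_cutoff) || is.null(p$meth_cutoff)) {
        stop("supply both hypometh_cutoff and meth_cutoff, or neither")
      }
      meth_cutoffs(p$hypometh_cutoff, p$meth_cutoff)
    } else {
      ctrl <- samples$sample_id[samples$group == "control"]
      estimate_cutoffs(beta_re[, intersect(ctrl, colnames(beta_re)), drop = FALSE])
    }
  })
  categories <- run_stage("classify", function() {
    categorize_probes(beta_re, samples, cutoffs, min_case = p$min_case)
  })
  links <- run_stage("link", function() {
    run_linking(categories, beta_re, expr, samples, genes, cutoffs,
                alpha = p$alpha, tf_only = p$tf_only,
                top_n_genes = p$top_n_genes)
  })
  tf_summary <- run_stage("rank", function() tally_links(links, genes))
  tf_ranking <- run_stage("rank", function() {
    rank_tfs(tf_summary, quadrant = p$quadrant, n = p$top_n)
  })

  paths <- c(re_annotation = file.path(config$out_dir, "re_annotation.tsv"),
             cutoffs = file.path(config$out_dir, "cutoffs.tsv"),
             categories = file.path(config$out_dir, "probe_categories.tsv"),
             links = file.path(config$out_dir, "links.tsv"),
             tf_summary = file.path(config$out_dir, "tf_summary.tsv"),
             tf_ranking = file.path(config$out_dir, "tf_ranking.tsv"),
             manifest = file.path(config$out_dir, "manifest.json"))
  readr::write_tsv(re_ann, paths["re_annotation"])
  readr::write_tsv(tidy(cutoffs), paths["cutoffs"])
  readr::write_tsv(dplyr::mutate(categories, category = as.character(.data$category)),
                   paths["categories"])
  write_link_table(links, paths["links"])
  readr::write_tsv(tf_summary, paths["tf_summary"])
  readr::write_tsv(tf_ranking, paths["tf_ranking"])

  manifest <- list(
    package = "methlink",
    version = as.character(utils::packageVersion("methlink")),
    params = p[!vapply(p, is.null, TRUE)],
    inputs = lapply(config$inputs, function(f) {
      lapply(as.character(f), function(x) list(path = x,
                                               md5 = unname(tools::md5sum(x))))
    }),
    n_re_probes = length(re_probes),
    n_links = nrow(links),
    n_significant = sum(links$significant)
  )
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE, pretty = TRUE)

  invisible(list(re_annotation = re_ann, cutoffs = cutoffs,
                 categories = categories, links = links,
                 tf_summary = tf_summary, tf_ranking = tf_ranking,
                 paths = paths))
}
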