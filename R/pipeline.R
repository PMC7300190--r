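# End-to-end pipelines: images -> morphology statistics, and quantification
# tables -> differential results, with provenance.

default_morphology_params <- function() {
  list(unsharp_sigma_px = 1.0, unsharp_weight = 0.6,
       threshold_method = "huang", min_area_px = 10L, clear_border = FALSE,
       distance_unit = "fov", leave_one_out = TRUE,
       ref_group = "CTRL", ref_treatment = "DMSO")
}

load_study_images <- function(study) {
  if (inherits(study, "image_study_set")) return(study)
  if (is.character(study) && file.exists(study)) {
    md <- utils::read.csv(study, stringsAsFactors = FALSE)
    need <- c("subject", "group", "treatment", "fov", "path_mito",
              "path_marker", "pixel_size_um")
    miss <- setdiff(setdiff(need, "pixel_size_um"), names(md))
    if (length(miss))
      stop("manifest missing columns: ", paste(miss, collapse = ", "))
    if (!"pixel_size_um" %in% names(md))
      stop("manifest must carry a pixel_size_um column")
    images <- lapply(seq_len(nrow(md)), function(i) {
      list(mito = read_calibrated_tiff(md$path_mito[i], md$pixel_size_um[i], "mito"),
           marker = read_calibrated_tiff(md$path_marker[i], md$pixel_size_um[i], "marker"))
    })
    md$index <- seq_len(nrow(md))
    return(structure(list(images = images, metadata = md, design = NULL),
                     class = "image_study_set"))
  }
  stop("`study` must be an image_study_set or a manifest CSV path")
}

#' Run the full morphology pipeline on an imaging study
#'
#' Per field of view: unsharp mask, automatic threshold (per slice on
#' stacks), cleanup, per-slice particle measurement pooled across slices,
#' and skeleton metrics on the max-projected mask. Study level: per-sample
#' KS distances to the pooled reference cell for every morphological
#' parameter, a balanced two-way ANOVA (mutation x treatment) of those
#' distances, and skeleton-metric Wilcoxon comparisons between genotype
#' groups in the reference treatment.
#'
#' @param study An `image_study_set` (from [simulate_population()]) or a
#'   manifest CSV path (columns subject, group, treatment, fov, path_mito,
#'   path_marker, pixel_size_um).
#' @param params Named list overriding [default_morphology_params()].
#' @param out_dir Optional directory: writes particles, skeleton, distances
#'   and ANOVA CSVs plus a provenance JSON.
#' @return List of class `morphology_results`: `particles`, `skeleton`,
#'   `distances`, `anova`, `wilcoxon`, `params`.
#' @export
run_morphology_pipeline <- function(study, params = list(), out_dir = NULL) {
  p <- utils::modifyList(default_morphology_params(), params)
  study <- load_study_images(study)
  md <- study$metadata
  if (!nrow(md)) stop("empty study: no image sets")
  particles <- list(); skeleton <- list(); dropped <- character(0)
  for (i in seq_len(nrow(md))) {
    img <- study$images[[md$index[i]]]$mito
    sharp <- unsharp_mask(img, p$unsharp_sigma_px, p$unsharp_weight)
    mask <- segment_image(sharp, p$threshold_method, p$min_area_px,
                          p$clear_border)
    meta <- list(subject = md$subject[i], group = md$group[i],
                 treatment = md$treatment[i], fov = md$fov[i])
    pt <- measure_particles(mask, meta = meta)
    if (!nrow(pt)) {
      warning(sprintf("empty segmentation for %s/%s fov %s: excluded",
                      md$subject[i], md$treatment[i], md$fov[i]))
      dropped <- c(dropped, sprintf("%s.%s.%s", md$subject[i],
                                    md$treatment[i], md$fov[i]))
      next
    }
    particles[[length(particles) + 1L]] <- pt
    sk <- skeleton_summary(mask)
    skeleton[[length(skeleton) + 1L]] <- data.frame(
      subject = md$subject[i], group = md$group[i],
      treatment = md$treatment[i], fov = md$fov[i],
      n_branches = sk$n_branches, n_junctions = sk$n_junctions,
      n_individuals = sk$n_individuals, n_networks = sk$n_networks,
      mean_branch_length_um = sk$mean_branch_length_um,
      mean_network_size = sk$mean_network_size,
      footprint_um2 = sk$footprint_um2)
  }
  particles <- do.call(rbind, particles)
  skeleton <- do.call(rbind, skeleton)
  distances <- list(); anova_tables <- list()
  for (param in morphology_parameters()) {
    dt <- sample_distance_table(particles, param, unit = p$distance_unit,
                                leave_one_out = p$leave_one_out,
                                ref_group = p$ref_group,
                                ref_treatment = p$ref_treatment)
    distances[[param]] <- dt
    anova_tables[[param]] <- two_way_anova(dt$D, dt$group, dt$treatment,
                                           names_ab = c("mutation", "treatment"))
  }
  distances <- do.call(rbind, distances)
  rownames(distances) <- NULL
  # skeleton comparison: genotype groups under the reference treatment
  wil <- list()
  sk_ref <- skeleton[skeleton$treatment == p$ref_treatment, , drop = FALSE]
  grps <- unique(sk_ref$group)
  if (length(grps) == 2L) {
    for (mcol in c("n_branches", "n_individuals", "n_networks",
                   "mean_branch_length_um", "mean_network_size",
                   "footprint_um2")) {
      x <- sk_ref[[mcol]][sk_ref$group == grps[1]]
      y <- sk_ref[[mcol]][sk_ref$group == grps[2]]
      w <- wilcoxon_rank_sum(x[is.finite(x)], y[is.finite(y)])
      wil[[length(wil) + 1L]] <- data.frame(metric = mcol, U = w$U, p = w$p,
                                            method = w$method)
    }
    wil <- do.call(rbind, wil)
  } else wil <- NULL
  res <- structure(list(particles = particles, skeleton = skeleton,
                        distances = distances, anova = anova_tables,
                        wilcoxon = wil, params = p, dropped = dropped),
                   class = "morphology_results")
  if (!is.null(out_dir)) write_morphology_results(res, out_dir)
  res
}

write_morphology_results <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$particles, file.path(out_dir, "particles.csv"),
                   row.names = FALSE)
  utils::write.csv(res$skeleton, file.path(out_dir, "skeleton.csv"),
                   row.names = FALSE)
  utils::write.csv(res$distances, file.path(out_dir, "distances.csv"),
                   row.names = FALSE)
  av <- do.call(rbind, lapply(names(res$anova), function(nm) {
    tb <- res$anova[[nm]]$table; tb$parameter <- nm; tb
  }))
  utils::write.csv(av, file.path(out_dir, "anova.csv"), row.names = FALSE)
  if (!is.null(res$wilcoxon))
    utils::write.csv(res$wilcoxon, file.path(out_dir, "skeleton_wilcoxon.csv"),
                     row.names = FALSE)
  prov <- list(pipeline = "morphology", package = "mitomorph",
               version = as.character(utils::packageVersion("mitomorph")),
               params = res$params, dropped = res$dropped)
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Run the proteomics differential pipeline
#'
#' Isoform collapse, differential filters, volcano table, ranked list and
#' (when gene sets are supplied) pre-ranked enrichment.
#'
#' @param table Quantification data.frame, or a CSV/TSV path with columns
#'   `accession`, replicate log2-ratio columns, `n_detected`, `log2_ratio`,
#'   `variance` and optionally `uniqueness`.
#' @param min_detected,fc_log2,alpha Filter thresholds
#'   (see [filter_differential()]).
#' @param gene_sets Optional named list (or GMT path) for enrichment.
#' @param n_perm,seed Permutation settings for the enrichment stage.
#' @param out_dir Optional output directory (filtered CSV, volcano CSV,
#'   RNK file, enrichment CSV, provenance JSON).
#' @return List of class `proteomics_results`: `diff`, `volcano`, `ranked`,
#'   `enrichment` (or NULL).
#' @export
run_proteomics_pipeline <- function(table, min_detected = 2L,
                                    fc_log2 = fc_threshold_log2(),
                                    alpha = 0.05, gene_sets = NULL,
                                    n_perm = 10000L, seed = NULL,
                                    out_dir = NULL) {
  if (is.character(table)) {
    sep <- if (grepl("\\.tsv$", table)) "\t" else ","
    table <- utils::read.table(table, header = TRUE, sep = sep,
                               stringsAsFactors = FALSE)
  }
  need <- c("accession", "log2_ratio", "variance", "n_detected")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("quant table missing columns: ",
                         paste(miss, collapse = ", "))
  if (!nrow(table)) stop("empty quantification table")
  collapsed <- collapse_isoforms(table)
  diff <- filter_differential(collapsed, min_detected, fc_log2, alpha)
  volcano <- volcano_table(collapsed, min_detected, fc_log2, alpha)
  ranked <- ranked_list(collapsed)
  enr <- NULL
  if (!is.null(gene_sets)) {
    if (is.character(gene_sets)) gene_sets <- read_gene_sets(gene_sets)
    enr <- preranked_enrichment(ranked, gene_sets, n_perm = n_perm, seed = seed)
  }
  res <- structure(list(diff = diff, volcano = volcano, ranked = ranked,
                        enrichment = enr),
                   class = "proteomics_results")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(diff$table, file.path(out_dir, "differential.csv"),
                     row.names = FALSE)
    utils::write.csv(volcano, file.path(out_dir, "volcano.csv"),
                     row.names = FALSE)
    write_rnk(ranked, file.path(out_dir, "ranked.rnk"))
    if (!is.null(enr))
      utils::write.csv(enr, file.path(out_dir, "enrichment.csv"),
                       row.names = FALSE)
    prov <- list(pipeline = "proteomics", package = "mitomorph",
                 version = as.character(utils::packageVersion("mitomorph")),
                 counts = as.list(diff$counts),
                 thresholds = diff$thresholds, n_perm = n_perm, seed = seed)
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  res
}

#' Load a YAML run configuration
#'
#' Thin wrapper over `yaml::read_yaml` for the analysis drivers; returns the
#' named parameter list as-is.
#' @param path YAML file path.
#' @return Named list.
#' @export
read_run_config <- function(path) yaml::read_yaml(path)
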