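#' Run the full analysis pipeline on synthetic or user data
#'
#' Orchestrates the stages end to end: simulate (optional) -> FPKM and
#' saturation -> pairwise DE and low-temperature consistency sets ->
#' functional-group resampling enrichment -> genotyping, distance and NJ
#' tree -> SSR detection and marker filtering. Every output is a plain-text
#' TSV/FASTA/JSON file under `out_dir`, and a `manifest.json` records the
#' configuration, its hash, the per-stage derived seeds and the checksum of
#' every written file, so a rerun with the same configuration reproduces
#' all outputs byte-identically.
#'
#' @param config a [sim_config()]; its `seed` drives every stage stream.
#' @param out_dir output directory (created; must be empty or absent unless
#'   `overwrite`).
#' @param stages character vector of stages to run, in pipeline order.
#' @param inputs named list of input file paths (counts, design, annotation,
#'   sites, transcripts) used when the `simulate` stage is disabled; all must
#'   exist before any stage runs.
#' @param n_iter resampling iterations for the enrichment stage.
#' @param alpha significance level for DE (BH-adjusted) and enrichment
#'   (Bonferroni-corrected).
#' @param subsample_sites genotype-matrix site subsample (NULL = all sites).
#' @param saturation_percentages,saturation_reps saturation-curve grid and
#'   thinning replicates.
#' @param dry_run if TRUE, list the planned stages and parameters without
#'   computing anything.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return (invisibly) the manifest list.
#' @export
run_pipeline <- function(config = sim_config(), out_dir,
                         stages = c("simulate", "expression", "de",
                                    "enrichment", "genotype", "ssr"),
                         inputs = NULL,
                         n_iter = 10000L, alpha = 0.05,
                         subsample_sites = NULL,
                         saturation_percentages = seq(10, 100, by = 10),
                         saturation_reps = 5L,
                         dry_run = FALSE, overwrite = FALSE) {
  validate_sim_config(config)
  known <- c("simulate", "expression", "de", "enrichment", "genotype", "ssr")
  stages <- match.arg(stages, known, several.ok = TRUE)
  plan <- list(stages = stages, seed = config$seed, n_iter = n_iter,
               alpha = alpha, subsample_sites = subsample_sites)
  if (dry_run) {
    message("dry run; planned stages: ", paste(stages, collapse = ", "))
    return(invisible(plan))
  }

  if (!"simulate" %in% stages) {
    need <- c("counts", "design")
    if ("enrichment" %in% stages) need <- c(need, "annotation")
    if ("genotype" %in% stages) need <- c(need, "sites")
    if ("ssr" %in% stages) need <- c(need, "transcripts")
    missing <- setdiff(need, names(inputs))
    if (length(missing))
      stop("missing input file(s) for the requested stages: ",
           paste(missing, collapse = ", "))
    absent <- unlist(inputs[need])[!file.exists(unlist(inputs[need]))]
    if (length(absent))
      stop("input file(s) not found: ", paste(absent, collapse = ", "))
  }

  if (dir.exists(out_dir) && length(dir(out_dir)) && !overwrite)
    stop("output directory ", out_dir, " is not empty")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(...) file.path(out_dir, ...)
  files <- character(0)
  emit <- function(f) files <<- c(files, f)

  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  state <- new.env(parent = emptyenv())

  ## ---- simulate ----
  if ("simulate" %in% stages) run_stage("simulate", function() {
    cd <- sim_counts(config)
    tx <- sim_transcripts(config)
    pil <- sim_pileups(config, transcripts = tx$sequences)
    ann <- sim_annotation(rownames(cd$counts), cd$truth, config)
    state$counts <- cd$counts; state$lengths <- cd$lengths
    state$design <- cd$design; state$annotation <- ann
    state$sites <- pil$sites; state$transcripts <- tx$sequences
    state$cds <- tx$cds_truth
    emit(write_counts_tsv(cd$counts, cd$lengths, path("counts.tsv")))
    emit(write_design_tsv(cd$design, path("design.tsv")))
    emit(write_annotation_tsv(ann, path("annotation.tsv")))
    emit(path("annotation.groups.tsv"))
    emit(write_sites_tsv(pil$sites, path("sites.tsv")))
    emit(write_fasta(tx$sequences, path("transcripts.fasta")))
    truth <- list(
      responsive_gene_ids = cd$truth$responsive_gene_ids,
      lfc = as.list(cd$truth$lfc),
      responds_in = cd$truth$responds_in,
      enriched_group_ids = attr(ann, "planted"),
      population = as.list(pil$truth$population),
      genotypes = as.data.frame(pil$truth$genotypes),
      ssr_truth = tx$ssr_truth, cds_truth = tx$cds_truth)
    jsonlite::write_json(truth, path("truth.json"), auto_unbox = TRUE,
                         digits = NA)
    emit(path("truth.json"))
  }) else {
    cm <- read_counts_tsv(inputs$counts)
    state$counts <- cm$counts; state$lengths <- cm$lengths
    state$design <- read_design_tsv(inputs$design)
    if (!is.null(inputs$annotation))
      state$annotation <- read_annotation_tsv(inputs$annotation)
    if (!is.null(inputs$sites)) state$sites <- read_sites_tsv(inputs$sites)
    if (!is.null(inputs$transcripts))
      state$transcripts <- read_fasta(inputs$transcripts)
    if (!is.null(inputs$cds)) state$cds <- read.delim(inputs$cds)
  }

  ## ---- expression ----
  if ("expression" %in% stages) run_stage("expression", function() {
    fpkm <- compute_fpkm(state$counts, state$lengths)
    state$fpkm <- fpkm
    df <- data.frame(gene_id = rownames(fpkm), fpkm, check.names = FALSE)
    write.table(df, path("fpkm.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    emit(path("fpkm.tsv"))
    sat <- saturation_curve(state$counts, state$lengths,
                            colnames(state$counts)[1L],
                            percentages = saturation_percentages,
                            n_reps = saturation_reps,
                            seed = derive_seed(config$seed, "saturation"))
    write.table(sat, path("saturation.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    emit(path("saturation.tsv"))
    dens <- density_summary(fpkm, state$design)
    write.table(dens, path("density.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    emit(path("density.tsv"))
  })

  ## ---- differential expression + consistency ----
  if ("de" %in% stages) run_stage("de", function() {
    design <- state$design
    temps <- tapply(design$temperature_C, design$group, unique)
    low <- names(temps)[temps < config$cold_cutoff]
    high <- names(temps)[temps >= config$cold_cutoff]
    if (!length(low) || !length(high))
      stop("need at least one group on each side of the cold cutoff")
    state$consistent <- list()
    state$de <- list()
    for (lg in low) {
      des <- lapply(high, function(hg)
        test_pairwise(state$counts, design, lg, hg, alpha = alpha))
      names(des) <- high
      for (hg in high) {
        f <- path(sprintf("de_%s_vs_%s.tsv", lg, hg))
        write.table(des[[hg]], f, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        emit(f)
      }
      cons <- consistent_degs(des, low_group = lg)
      f <- path(sprintf("consistent_degs_%s.tsv", lg))
      write.table(cons, f, sep = "\t", quote = FALSE, row.names = FALSE)
      emit(f)
      state$de[[lg]] <- des
      state$consistent[[lg]] <- cons
    }
    if (length(low) >= 2L) {
      lo <- low[order(unlist(temps[low]))]
      direct <- test_pairwise(state$counts, design, lo[1L], lo[2L],
                              alpha = alpha)
      ov <- overlap_analysis(state$consistent[[lo[1L]]],
                             state$consistent[[lo[2L]]],
                             de_direct = direct,
                             de_results_a = state$de[[lo[1L]]],
                             de_results_b = state$de[[lo[2L]]])
      jsonlite::write_json(
        lapply(ov, function(v)
          if (inherits(v, "table")) as.list(v) else v),
        path("overlap.json"), auto_unbox = TRUE, digits = NA)
      emit(path("overlap.json"))
      state$overlap <- ov
    }
    if (!is.null(state$fpkm)) {
      degs <- sort(unique(unlist(lapply(state$consistent, `[[`, "gene_id"))))
      if (length(degs)) {
        em <- deg_expression_matrix(state$fpkm, degs)
        write.table(data.frame(gene_id = rownames(em), em,
                               check.names = FALSE),
                    path("deg_log10_fpkm.tsv"), sep = "\t", quote = FALSE,
                    row.names = FALSE)
        emit(path("deg_log10_fpkm.tsv"))
      }
    }
  })

  ## ---- enrichment ----
  if ("enrichment" %in% stages) run_stage("enrichment", function() {
    if (is.null(state$annotation)) stop("no annotation available")
    fpkm <- state$fpkm %||% compute_fpkm(state$counts, state$lengths)
    background <- rownames(fpkm)[rowSums(fpkm > 0) > 0]
    state$background <- background
    for (lg in names(state$consistent %||% list())) {
      degs <- intersect(state$consistent[[lg]]$gene_id, background)
      if (!length(degs)) next
      enr <- enrichment_test(degs, background, state$annotation,
                             n_iter = n_iter, alpha = alpha,
                             seed = derive_seed(config$seed,
                                                paste0("enrich_", lg)))
      f <- path(sprintf("enrichment_%s.tsv", lg))
      write.table(enr, f, sep = "\t", quote = FALSE, row.names = FALSE)
      emit(f)
      tab <- go_class_table(state$annotation,
                            list(all = background, DEG = degs),
                            enrichment = enr)
      f2 <- path(sprintf("go_classification_%s.tsv", lg))
      write.table(tab, f2, sep = "\t", quote = FALSE, row.names = FALSE)
      emit(f2)
      state$enrichment[[lg]] <- enr
    }
  })

  ## ---- genotype / structure ----
  if ("genotype" %in% stages) run_stage("genotype", function() {
    if (is.null(state$sites)) stop("no variant sites available")
    filtered <- select_sites(quality_filter(state$sites))
    snp <- filtered[nchar(filtered$ref) == 1L & nchar(filtered$alt) == 1L, ,
                    drop = FALSE]
    snp <- as_site_table(snp)
    nsub <- subsample_sites
    if (!is.null(nsub)) nsub <- min(nsub, nrow(snp))
    gm <- build_genotype_matrix(snp, n_subsample = nsub,
                                seed = derive_seed(config$seed, "genotype"))
    state$genotypes <- gm
    emit(write_genotype_nexus(gm, path("genotypes.nex")))
    emit(write_genotype_fasta(gm, path("genotypes.fasta")))
    emit(write_genotype_phylip(gm, path("genotypes.phy")))
    d <- genotype_distance(gm)
    tree <- nj_tree(d)
    ape::write.tree(tree, path("nj_tree.nwk"))
    emit(path("nj_tree.nwk"))
    state$tree <- tree
    if (!is.null(state$transcripts) && !is.null(state$cds) &&
        nrow(state$cds)) {
      eff <- coding_effect(state$sites, state$transcripts, state$cds)
      write.table(eff, path("coding_effects.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      emit(path("coding_effects.tsv"))
      rr <- ratio_by_gene(eff)
      write.table(rr, path("nonsyn_syn_ratio.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      emit(path("nonsyn_syn_ratio.tsv"))
    }
    indels <- indel_marker_filter(state$sites)
    if (nrow(indels)) {
      write.table(as.data.frame(indels)[, c("gene_id", "pos", "ref", "alt")],
                  path("indel_markers.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      emit(path("indel_markers.tsv"))
    }
  })

  ## ---- SSR ----
  if ("ssr" %in% stages) run_stage("ssr", function() {
    if (is.null(state$transcripts)) stop("no transcript sequences available")
    ssrs <- find_ssrs(state$transcripts)
    write.table(ssrs, path("ssrs.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    emit(path("ssrs.tsv"))
    markers <- ssr_marker_filter(ssrs)
    write.table(markers, path("ssr_markers.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    emit(path("ssr_markers.tsv"))
    state$ssrs <- ssrs
  })

  ## ---- manifest ----
  cfg_file <- path("config.json")
  jsonlite::write_json(unclass(config), cfg_file, auto_unbox = TRUE,
                       digits = NA)
  emit(cfg_file)
  manifest <- list(
    tool = "coldacc",
    version = as.character(utils::packageVersion("coldacc")),
    seed = config$seed,
    config_hash = unname(tools::md5sum(cfg_file)),
    stage_seeds = setNames(
      lapply(c("counts", "annotation", "pileups", "transcripts",
               "saturation", "genotype"),
             function(s) derive_seed(config$seed, s)),
      c("counts", "annotation", "pileups", "transcripts", "saturation",
        "genotype")),
    parameters = plan,
    files = lapply(setNames(nm = basename(files)), function(f)
      unname(tools::md5sum(file.path(out_dir, f))))
  )
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(c(manifest, list(state = state)))
}
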