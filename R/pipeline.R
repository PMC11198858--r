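#' Read and validate a pipeline configuration
#'
#' YAML configuration with a `samples` list (path, sample_id, species,
#' condition), optional `reference_species`, `gene_map` path, `gene_sets`
#' GMT path, parameter blocks `qc`, `divik`, `effect`, `linkage`, and a
#' global `seed`. Every referenced path must exist at load time.
#'
#' @param path YAML file.
#' @return validated config list.
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$samples) || length(cfg$samples) == 0)
    stop("config error: no samples declared")
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  for (i in seq_along(cfg$samples)) {
    s <- cfg$samples[[i]]
    for (f in c("path", "sample_id", "species", "condition"))
      if (is.null(s[[f]]))
        stop("config error: sample ", i, " missing field '", f, "'")
    cfg$samples[[i]]$path <- resolve(s$path)
    if (!dir.exists(cfg$samples[[i]]$path) &&
        !file.exists(cfg$samples[[i]]$path))
      stop("config error: sample path does not exist: ", s$path)
  }
  for (f in c("gene_map", "gene_sets")) {
    if (!is.null(cfg[[f]])) {
      cfg[[f]] <- resolve(cfg[[f]])
      if (!file.exists(cfg[[f]]))
        stop("config error: ", f, " path does not exist: ", cfg[[f]])
    }
  }
  cfg$seed <- as.integer(cfg$seed %||% 1)
  if (is.null(cfg$reference_species))
    cfg$reference_species <- cfg$samples[[1]]$species
  cfg
}

#' Run the full effect-size-profiling pipeline
#'
#' Executes qc -> cluster -> profile -> link -> ratio -> consensus (and
#' optional enrichment) over the configured samples and writes every
#' stage artifact plus a machine-readable run manifest into `out_dir`.
#' Stages communicate through on-disk artifacts; re-running with the same
#' configuration and seed reproduces all outputs bitwise. A single
#' global seed fans out deterministically to per-stage seeds.
#'
#' Artifacts: `qc_report.csv`; per sample `clusters_<id>.tsv` (barcode,
#' cluster), `tree_<id>.json`, `profiles_<id>.csv` (genes x clusters
#' effect sizes); per query sample `linkage_<id>.csv` (correlations) and
#' `assignment_<id>.tsv`; per species `ratios_<species>_<type>.csv`;
#' `consensus.csv`; optional `enrichment.csv`; `manifest.json`.
#'
#' @param config path to a YAML config or a list from
#'   [readPipelineConfig()].
#' @param out_dir run directory, created if needed.
#' @return the manifest list, invisibly.
#' @export
runPipeline <- function(config, out_dir) {
  cfg <- if (is.character(config)) readPipelineConfig(config) else config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  qcp <- do.call(qcParams, cfg$qc %||% list())
  dvp <- do.call(divikParams,
                 c(cfg$divik %||% list(),
                   if (is.null(cfg$divik$seed)) list(seed = cfg$seed + 1L)))
  eff <- utils::modifyList(
    list(negligible = 0.1, select = 1.5, consensus = 1.0),
    cfg$effect %||% list())
  lkg <- utils::modifyList(list(min_shared_genes = 50, weighting = "query"),
                           cfg$linkage %||% list())
  gene_map <- if (!is.null(cfg$gene_map)) readGeneMap(cfg$gene_map)
              else GeneMap()
  manifest <- list(seed = cfg$seed, stages = list(),
                   parameters = list(qc = unclass(qcp),
                                     divik = unclass(dvp),
                                     effect = eff, linkage = lkg))
  stageDone <- function(name, outputs) {
    manifest$stages[[name]] <<- list(
      status = "completed", outputs = outputs,
      checksums = stats::setNames(
        as.list(unname(tools::md5sum(file.path(out_dir, outputs)))),
        outputs))
  }
  fail <- function(name, sample, e) {
    manifest$stages[[name]] <<- list(status = "FAILED", sample = sample,
                                     error = conditionMessage(e))
    writeManifest(manifest, out_dir)
    stop("stage '", name, "' failed for sample '", sample, "': ",
         conditionMessage(e))
  }

  # --- qc + normalisation, per sample -------------------------------
  norm <- list()
  for (s in cfg$samples) {
    tryCatch({
      cm <- read10x(s$path, s$sample_id, s$species, s$condition)
      cm <- filterCells(filterGenes(cm), qcp)
      norm[[s$sample_id]] <- logNormalize(cm, qcp)
    }, error = function(e) fail("qc", s$sample_id, e))
  }
  qc_file <- "qc_report.csv"
  utils::write.csv(qcReport(norm), file.path(out_dir, qc_file),
                   row.names = FALSE)
  stageDone("qc", qc_file)

  # --- clustering ----------------------------------------------------
  trees <- list()
  clus_files <- character()
  for (sid in names(norm)) {
    tryCatch({
      trees[[sid]] <- divik(norm[[sid]], dvp)
      labs <- leafLabels(trees[[sid]])
      f1 <- paste0("clusters_", sid, ".tsv")
      utils::write.table(data.frame(barcode = names(labs), cluster = labs),
                         file.path(out_dir, f1), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      f2 <- paste0("tree_", sid, ".json")
      jsonlite::write_json(treeToList(trees[[sid]]),
                           file.path(out_dir, f2), auto_unbox = TRUE,
                           digits = NA)
      clus_files <- c(clus_files, f1, f2)
    }, error = function(e) fail("cluster", sid, e))
  }
  stageDone("cluster", clus_files)

  # --- effect-size profiles ------------------------------------------
  profiles <- list()
  prof_files <- character()
  for (sid in names(norm)) {
    tryCatch({
      profiles[[sid]] <- clusterProfiles(norm[[sid]], trees[[sid]])
      f <- paste0("profiles_", sid, ".csv")
      utils::write.csv(esMatrix(profiles[[sid]]),
                       file.path(out_dir, f))
      prof_files <- c(prof_files, f)
    }, error = function(e) fail("profile", sid, e))
  }
  stageDone("profile", prof_files)

  # --- linkage of every sample to the reference sample ---------------
  # the reference is the control sample of the reference species; its
  # cluster labels serve as cell-type identities for all other samples
  meta <- lapply(cfg$samples, function(s)
    s[c("sample_id", "species", "condition")])
  names(meta) <- vapply(meta, `[[`, "", "sample_id")
  ref_hit <- Filter(function(m) m$species == cfg$reference_species &&
                      m$condition == "control", meta)
  if (!length(ref_hit))
    stop("config error: no control sample for reference species '",
         cfg$reference_species, "'")
  ref_sid <- ref_hit[[1]]$sample_id
  links <- list()
  link_files <- character()
  for (sid in names(norm)) {
    if (sid == ref_sid) next
    tryCatch({
      gm <- if (meta[[sid]]$species == cfg$reference_species) GeneMap()
            else gene_map
      links[[sid]] <- linkProfiles(profiles[[sid]], profiles[[ref_sid]],
                                   gm,
                                   min_shared_genes = lkg$min_shared_genes)
      f1 <- paste0("linkage_", sid, ".csv")
      utils::write.csv(links[[sid]]@corr, file.path(out_dir, f1))
      f2 <- paste0("assignment_", sid, ".tsv")
      utils::write.table(assignments(links[[sid]]),
                         file.path(out_dir, f2), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      link_files <- c(link_files, f1, f2)
    }, error = function(e) fail("link", sid, e))
  }
  stageDone("link", link_files)

  # --- treatment/control ratios per species --------------------------
  cellTypeOf <- function(sid, cl) {
    if (sid == ref_sid) return(cl)
    a <- assignments(links[[sid]])
    a$reference[match(cl, a$query)]
  }
  ratio_files <- character()
  ratios <- list()
  for (sp in unique(vapply(meta, `[[`, "", "species"))) {
    sid_t <- names(Filter(function(m) m$species == sp &&
                            m$condition == "stimulated", meta))
    sid_c <- names(Filter(function(m) m$species == sp &&
                            m$condition == "control", meta))
    if (!length(sid_t) || !length(sid_c)) next
    prof_t <- profiles[[sid_t[1]]]
    prof_c <- profiles[[sid_c[1]]]
    for (cl_t in names(prof_t)) {
      ty <- cellTypeOf(sid_t[1], cl_t)
      if (is.na(ty)) next
      cl_c <- names(prof_c)[vapply(names(prof_c), function(cl)
        identical(cellTypeOf(sid_c[1], cl), ty), logical(1))]
      if (!length(cl_c)) next
      tryCatch({
        rt <- effectSizeRatios(prof_t[[cl_t]], prof_c[[cl_c[1]]],
                               cell_type = ty,
                               negligible_threshold = eff$negligible,
                               selection_threshold = eff$select)
        ratios[[paste(sp, ty, sep = ":")]] <- rt
        f <- sprintf("ratios_%s_%s.csv", sp, gsub("[^A-Za-z0-9._-]", "_", ty))
        utils::write.csv(ratioTable(rt), file.path(out_dir, f),
                         row.names = FALSE)
        ratio_files <- c(ratio_files, f)
      }, error = function(e) fail("ratio", paste(sp, cl_t), e))
    }
  }
  stageDone("ratio", ratio_files)

  # --- cross-species consensus ---------------------------------------
  cons_rows <- list()
  species <- unique(vapply(meta, `[[`, "", "species"))
  if (length(species) == 2) {
    ref <- cfg$reference_species
    qry <- setdiff(species, ref)
    for (ty in unique(sub("^[^:]+:", "", names(ratios)))) {
      ka <- paste(ref, ty, sep = ":")
      kb <- paste(qry, ty, sep = ":")
      if (is.null(ratios[[ka]]) || is.null(ratios[[kb]])) next
      cc <- crossSpeciesConsensus(ratios[[ka]], ratios[[kb]], gene_map,
                                  threshold = eff$consensus)
      if (nrow(cc)) cons_rows[[ty]] <- cbind(cell_type = ty, cc)
    }
  }
  cons <- if (length(cons_rows)) do.call(rbind, cons_rows) else
    data.frame(cell_type = character(), gene_a = character(),
               gene_b = character(), ratio_a = numeric(),
               ratio_b = numeric())
  utils::write.csv(cons, file.path(out_dir, "consensus.csv"),
                   row.names = FALSE)
  stageDone("consensus", "consensus.csv")

  # --- optional enrichment -------------------------------------------
  if (!is.null(cfg$gene_sets) && length(ratios)) {
    sets <- readGmt(cfg$gene_sets)
    ref_tabs <- ratios[startsWith(names(ratios),
                                  paste0(cfg$reference_species, ":"))]
    if (length(ref_tabs)) {
      univ <- unique(unlist(lapply(ref_tabs,
                                   function(r) ratioTable(r)$gene)))
      sel <- unique(unlist(lapply(ref_tabs, function(r) {
        tb <- ratioTable(r)
        tb$gene[tb$selected]
      })))
      en <- hypergeomEnrichment(sel, univ, sets)
      utils::write.csv(en, file.path(out_dir, "enrichment.csv"),
                       row.names = FALSE)
      stageDone("enrich", "enrichment.csv")
    }
  }

  writeManifest(manifest, out_dir)
  invisible(manifest)
}

writeManifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}
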