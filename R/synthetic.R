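#' Parameters of the two-species simulator
#'
#' Defaults describe a desk-scale analogue of a two-species PBMC
#' stimulation experiment: four shared immune cell types dominated by a
#' responsive monocyte population, negative-binomial counts with
#' species-specific library sizes and per-gene species batch offsets
#' large enough to mix species under naive joint clustering, a
#' mitochondrial gene block for QC, planted QC violators, and planted
#' stimulation-responsive genes. Planted response genes are drawn from
#' well-expressed genes and carry a modest baseline enrichment
#' (`response_baseline_fold`) in the responsive cell type — mirroring
#' inflammatory genes, which are myeloid-expressed at rest and amplified
#' by stimulation — so that their control-sample effect sizes clear the
#' negligible-effect filter that the ratio analysis applies.
#'
#' @param n_genes genes per species (default 2000), mitochondrial genes
#'   excluded.
#' @param shared_fraction fraction of symbols shared between species
#'   (default 0.8); the rest are species-private.
#' @param cell_types data.frame with columns `name` and `fraction`
#'   (fractions sum to 1).
#' @param n_marker_genes markers per cell type (default 40).
#' @param marker_fold expression fold of a marker in its cell type
#'   (default 8).
#' @param n_cells cells per sample (default 1500).
#' @param n_response_genes planted stimulation-responsive genes
#'   (default 50).
#' @param response_fold extra fold in stimulated responsive-type cells
#'   (default 4).
#' @param response_baseline_fold baseline enrichment of response genes
#'   in the responsive cell type, both conditions (default 2).
#' @param responsive_cell_type default `"Monocytes"`.
#' @param nb_dispersion negative-binomial dispersion (default 0.3).
#' @param lib_lognormal list of c(meanlog, sdlog) per species for the
#'   cell library-size factor.
#' @param species_batch_sd sd of the per-gene, per-species log batch
#'   offset (default 0.3).
#' @param n_mito_genes mitochondrial pseudo-genes (default 10).
#' @param mito_fraction_beta Beta(a, b) of per-cell mitochondrial
#'   fraction (default c(2, 198), mean 1%).
#' @param qc_low_feature_fraction,qc_high_mito_fraction fractions of
#'   cells forced to violate the feature / mito QC rules (default 0.02
#'   each).
#' @param species_names length-2 character vector.
#' @param seed integer RNG seed.
#' @return list of class `SimParams`.
#' @export
simParams <- function(n_genes = 2000, shared_fraction = 0.8,
                      cell_types = data.frame(
                        name = c("Monocytes", "Tcells", "Bcells", "NKcells"),
                        fraction = c(0.3, 0.4, 0.2, 0.1)),
                      n_marker_genes = 40, marker_fold = 8,
                      n_cells = 1500, n_response_genes = 50,
                      response_fold = 4, response_baseline_fold = 2,
                      responsive_cell_type = "Monocytes",
                      nb_dispersion = 0.3,
                      lib_lognormal = list(c(0, 0.3), c(0.3, 0.3)),
                      species_batch_sd = 0.3, n_mito_genes = 10,
                      mito_fraction_beta = c(2, 198),
                      qc_low_feature_fraction = 0.02,
                      qc_high_mito_fraction = 0.02,
                      species_names = c("speciesA", "speciesB"),
                      seed = 1) {
  if (abs(sum(cell_types$fraction) - 1) > 1e-9)
    stop("cell type fractions must sum to 1")
  stopifnot(marker_fold > 1, response_fold >= 1, nb_dispersion > 0,
            responsive_cell_type %in% cell_types$name,
            length(species_names) == 2)
  structure(as.list(environment()), class = "SimParams")
}

#' Simulate a two-species stimulation experiment
#'
#' Generates four [CountMatrix-class] samples (species x condition) with
#' shared cell types, planted markers, planted stimulation-responsive
#' genes in one cell type, species batch offsets, mitochondrial genes and
#' planted QC violators, plus the ground truth and the cross-species gene
#' map. Deterministic given `params$seed`.
#'
#' Count model, on the mean scale of a negative binomial with dispersion
#' `nb_dispersion`:
#' `mu[g, c] = baseline[g] * marker_fold^[g marks type(c)]
#'   * response_baseline_fold^[g response, type(c) responsive]
#'   * response_fold^[g response, type(c) responsive, stimulated]
#'   * exp(batch[g, species]) * lib[c]`.
#'
#' @param params [simParams()].
#' @return list with `samples` (named list of four [CountMatrix-class]),
#'   `truth` (per-sample cell types, per-gene marker assignment,
#'   response genes, planted QC violators, per-sample expected gene
#'   means before the planted QC artefacts) and `gene_map`
#'   ([GeneMap-class] over shared non-mitochondrial symbols).
#' @export
simulateTwoSpecies <- function(params = simParams()) {
  p <- params
  withSeed(p$seed, {
    n_shared <- round(p$shared_fraction * p$n_genes)
    n_priv <- p$n_genes - n_shared
    shared <- sprintf("GS%04d", seq_len(n_shared))
    priv <- lapply(1:2, function(s)
      sprintf("%s_G%04d", toupper(substr(p$species_names[s], 1, 3)),
              seq_len(n_priv)))
    mito <- sprintf("MT-%02d", seq_len(p$n_mito_genes))

    base_shared <- stats::rlnorm(n_shared, meanlog = -1, sdlog = 1.2)
    base_priv <- lapply(1:2, function(s)
      stats::rlnorm(n_priv, meanlog = -1, sdlog = 1.2))

    types <- p$cell_types$name
    # markers and response genes: disjoint subsets of the shared genes
    pool <- sample(n_shared)
    resp_idx <- pool[seq_len(p$n_response_genes)]
    base_shared[resp_idx] <- stats::rlnorm(p$n_response_genes,
                                           meanlog = 0.5, sdlog = 0.4)
    pool <- pool[-seq_len(p$n_response_genes)]
    marker_idx <- list()
    for (ty in types) {
      marker_idx[[ty]] <- pool[seq_len(p$n_marker_genes)]
      pool <- pool[-seq_len(p$n_marker_genes)]
    }
    marker_of <- rep(NA_character_, n_shared)
    for (ty in types) marker_of[marker_idx[[ty]]] <- ty

    batch <- lapply(1:2, function(s)
      stats::rnorm(n_shared + n_priv, 0, p$species_batch_sd))
    mito_w <- lapply(1:2, function(s) {
      w <- stats::rlnorm(p$n_mito_genes, 0, 0.5)
      w / sum(w)
    })

    # per-type mean multipliers on the shared+private gene vector
    foldMatrix <- function(stim) {
      fm <- matrix(1, n_shared + n_priv, length(types),
                   dimnames = list(NULL, types))
      for (ty in types) fm[marker_idx[[ty]], ty] <- p$marker_fold
      fm[resp_idx, p$responsive_cell_type] <-
        fm[resp_idx, p$responsive_cell_type] * p$response_baseline_fold *
        (if (stim) p$response_fold else 1)
      fm
    }

    n_type <- round(p$cell_types$fraction * p$n_cells)
    n_type[1] <- p$n_cells - sum(n_type[-1])
    type_vec <- rep(types, n_type)

    samples <- list()
    truth_types <- list()
    truth_qc <- list()
    expected_means <- list()
    for (s in 1:2) {
      genes <- c(shared, priv[[s]], mito)
      baseline <- c(base_shared, base_priv[[s]])
      for (cond in c("control", "stimulated")) {
        sid <- paste(p$species_names[s], cond, sep = "_")
        fm <- foldMatrix(cond == "stimulated")
        lib <- stats::rlnorm(p$n_cells, p$lib_lognormal[[s]][1],
                             p$lib_lognormal[[s]][2])
        mu <- (baseline * exp(batch[[s]])) %o% rep(1, p$n_cells)
        mu <- mu * fm[, match(type_vec, types)]
        mu <- sweep(mu, 2, lib, `*`)
        cts <- matrix(stats::rnbinom(length(mu), size = 1 / p$nb_dispersion,
                                     mu = mu), nrow(mu), ncol(mu))
        # mitochondrial block: per-cell fraction from the Beta, a planted
        # subset forced above the QC threshold
        f <- stats::rbeta(p$n_cells, p$mito_fraction_beta[1],
                          p$mito_fraction_beta[2])
        n_hi <- round(p$qc_high_mito_fraction * p$n_cells)
        n_lo <- round(p$qc_low_feature_fraction * p$n_cells)
        planted <- sample(p$n_cells, n_hi + n_lo)
        hi_mito <- planted[seq_len(n_hi)]
        low_feat <- planted[n_hi + seq_len(n_lo)]
        f[hi_mito] <- stats::runif(n_hi, 0.15, 0.30)
        tot <- colSums(cts)
        mito_tot <- round(f / (1 - f) * pmax(tot, 1))
        mito_cts <- vapply(seq_len(p$n_cells), function(i)
          stats::rmultinom(1, mito_tot[i], mito_w[[s]])[, 1],
          numeric(p$n_mito_genes))
        cts <- rbind(cts, mito_cts)
        # planted low-complexity cells: keep at most 150 detected genes
        for (i in low_feat) {
          nz <- which(cts[, i] > 0)
          if (length(nz) > 150) cts[setdiff(nz, sample(nz, 150)), i] <- 0
        }
        expected_means[[sid]] <- stats::setNames(rowMeans(mu),
                                                 c(shared, priv[[s]]))
        barcodes <- sprintf("%s-%05d", sid, seq_len(p$n_cells))
        cm <- CountMatrix(cts, gene_ids = genes, barcodes = barcodes,
                          sample_id = sid, species = p$species_names[s],
                          condition = cond, mito_prefix = "MT-")
        samples[[sid]] <- cm
        truth_types[[sid]] <- stats::setNames(type_vec, barcodes)
        truth_qc[[sid]] <- list(high_mito = barcodes[hi_mito],
                                low_features = barcodes[low_feat])
      }
    }
    gene_map <- GeneMap(data.frame(a = shared, b = shared))
    truth <- list(cell_types = truth_types,
                  marker_of = stats::setNames(marker_of, shared),
                  response_genes = shared[resp_idx],
                  qc_violators = truth_qc,
                  expected_means = expected_means,
                  responsive_cell_type = p$responsive_cell_type)
    list(samples = samples, truth = truth, gene_map = gene_map)
  })
}

#' Simulate isotropic Gaussian cluster fixtures
#'
#' Blobs of unit-variance Gaussians on `n_informative` features (cluster
#' centres separated by at least `separation_sigmas`), pure N(0,1) noise
#' on the remaining features. Fixture for clustering and
#' partition-comparison tests.
#'
#' @param n_points total observations.
#' @param n_clusters number of blobs (>= 1).
#' @param separation_sigmas minimum pairwise centre distance in units of
#'   the within-cluster standard deviation; must be positive.
#' @param n_informative informative features (default 5).
#' @param n_noise_features noise features (default 15).
#' @param seed integer seed.
#' @return list with `matrix` (n_points x features) and `labels`
#'   (integer per point).
#' @export
simulateGaussianClusters <- function(n_points, n_clusters,
                                     separation_sigmas,
                                     n_informative = 5,
                                     n_noise_features = 15, seed = 1) {
  stopifnot(n_clusters >= 1)
  if (separation_sigmas <= 0) stop("separation must be positive")
  withSeed(seed, {
    sizes <- rep(n_points %/% n_clusters, n_clusters)
    sizes[seq_len(n_points %% n_clusters)] <-
      sizes[seq_len(n_points %% n_clusters)] + 1
    labels <- rep(seq_len(n_clusters), sizes)
    centers <- matrix(0, n_clusters, n_informative)
    if (n_clusters > 1) {
      centers <- matrix(stats::rnorm(n_clusters * n_informative),
                        n_clusters, n_informative)
      dmin <- min(stats::dist(centers))
      while (dmin < 1e-6) {
        centers <- matrix(stats::rnorm(n_clusters * n_informative),
                          n_clusters, n_informative)
        dmin <- min(stats::dist(centers))
      }
      centers <- centers * separation_sigmas / dmin
    }
    inf <- centers[labels, , drop = FALSE] +
      matrix(stats::rnorm(n_points * n_informative), n_points)
    noise <- matrix(stats::rnorm(n_points * n_noise_features), n_points)
    m <- cbind(inf, noise)
    colnames(m) <- c(sprintf("inf%02d", seq_len(n_informative)),
                     sprintf("noise%02d", seq_len(n_noise_features)))
    rownames(m) <- sprintf("obs%04d", seq_len(n_points))
    list(matrix = m, labels = labels)
  })
}
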