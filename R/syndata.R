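#' Configuration for the synthetic TAM dataset generator
#'
#' Defines the statistical structure of a simulated regional (core/periphery)
#' tumor-associated-macrophage single-cell experiment: negative-binomial
#' counts, disjoint gene programs, a latent branched maturation trajectory,
#' region-dependent ontogeny mixing, and activation-state-dependent
#' ligand/receptor panels. Default cell numbers follow the regional sample
#' sizes of the kind of study this generator emulates (2343 core and 1246
#' periphery cells).
#'
#' @param n_cells_core,n_cells_periphery number of cells per region.
#' @param n_genes total genes (programs plus background).
#' @param nb_dispersion shared negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param depth_mean expected library size per cell.
#' @param signature_sizes named integer vector giving the gene count of each
#'   program block: `ontogeny_bmdm`, `ontogeny_mg`, `polarization`,
#'   `differentiation`, `ligand`, `receptor`, `pathway1`, `pathway2`.
#'   `polarization` and `differentiation` must be even (their blocks split
#'   into positively and negatively loaded halves).
#' @param trajectory_branch_time latent time of the branch point, strictly
#'   inside (0, 1).
#' @param effect_size log-scale loading of the gene programs (0 = null data).
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_cells_core = 2343, n_cells_periphery = 1246,
                         n_genes = 2000, nb_dispersion = 0.3,
                         depth_mean = 10000,
                         signature_sizes = c(ontogeny_bmdm = 40,
                                             ontogeny_mg = 40,
                                             polarization = 40,
                                             differentiation = 40,
                                             ligand = 20, receptor = 20,
                                             pathway1 = 30, pathway2 = 30),
                         trajectory_branch_time = 0.4,
                         effect_size = 1, seed = 1) {
  if (n_cells_core <= 0 || n_cells_periphery <= 0 || n_genes <= 0)
    stop("cell and gene counts must be positive")
  if (trajectory_branch_time <= 0 || trajectory_branch_time >= 1)
    stop("trajectory_branch_time must be strictly inside (0, 1)")
  stopifnot(nb_dispersion > 0, depth_mean > 0, effect_size >= 0)
  req <- c("ontogeny_bmdm", "ontogeny_mg", "polarization", "differentiation",
           "ligand", "receptor", "pathway1", "pathway2")
  miss <- setdiff(req, names(signature_sizes))
  if (length(miss)) stop("signature_sizes missing: ", paste(miss, collapse = ", "))
  if (any(signature_sizes <= 0)) stop("signature sizes must be positive")
  if (signature_sizes["polarization"] %% 2 != 0 ||
      signature_sizes["differentiation"] %% 2 != 0)
    stop("polarization and differentiation block sizes must be even")
  if (sum(signature_sizes) + 10 > n_genes)
    stop("n_genes must exceed the program blocks by at least 10 background genes")
  structure(list(n_cells_core = as.integer(n_cells_core),
                 n_cells_periphery = as.integer(n_cells_periphery),
                 n_genes = as.integer(n_genes),
                 nb_dispersion = nb_dispersion, depth_mean = depth_mean,
                 signature_sizes = signature_sizes[req],
                 trajectory_branch_time = trajectory_branch_time,
                 effect_size = effect_size, seed = as.integer(seed)),
            class = "synth_config")
}

# Disjoint program labels for every gene, in a fixed order.
synth_gene_programs <- function(config) {
  sz <- config$signature_sizes
  prog <- c(rep("ontogeny-BMDM", sz["ontogeny_bmdm"]),
            rep("ontogeny-MG", sz["ontogeny_mg"]),
            rep("polarization", sz["polarization"]),
            rep("differentiation", sz["differentiation"]),
            rep("ligand", sz["ligand"]),
            rep("receptor", sz["receptor"]),
            rep("pathway-1", sz["pathway1"]),
            rep("pathway-2", sz["pathway2"]))
  prog <- c(prog, rep("background", config$n_genes - length(prog)))
  data.frame(gene_id = sprintf("G%05d", seq_len(config$n_genes)),
             program = prog, stringsAsFactors = FALSE)
}

#' Generate a synthetic single-cell TAM dataset with ground truth
#'
#' Draws per-cell latent structure (uniform latent time; a trunk splitting
#' into branches A and B at `trajectory_branch_time` with equal probability;
#' region-dependent ontogeny fraction, Beta(8,2) in core and Beta(2,8) in
#' periphery), builds a log-linear mean structure in which each gene program
#' responds to its latent covariate with slope `effect_size`, rescales each
#' cell's means to its target library size, and samples negative-binomial
#' counts with shared dispersion.
#'
#' Program wiring: ontogeny blocks load on the ontogeny fraction (BMDM up,
#' microglia down); the differentiation block rises with latent time
#' (positive half) or falls (negative half); the polarization block drifts
#' with maturation in a region-dependent direction (pro-inflammatory in
#' core, anti-inflammatory in periphery), more strongly on branch A than
#' branch B (negative half mirrored); ligand genes are up in immature
#' states (M0, M1-pre) and receptor genes in pro-inflammatory states
#' (M1-pre, M1-like); pathway-1 genes rise along branch A only; pathway-2
#' genes switch on in the terminal fifth of branch B.
#'
#' The true activation state is the quadrant of (maturity, polarization):
#' latent time above 0.5 counts as mature, branch-A polarization as
#' pro-inflammatory.
#'
#' @param config a [synth_config].
#' @return List with `counts` (a [tam_counts]), `truth` (list: `cells`
#'   data.frame with `cell_id`, `latent_time`, `branch_id`,
#'   `ontogeny_fraction`, `activation_state_true`; `genes` data.frame with
#'   `gene_id`, `program`), `signatures` (named gene lists: `bmdm`, `mg`,
#'   `pol_pos`, `pol_neg`, `dif_pos`, `dif_neg`, `ligands`, `receptors`,
#'   `pathway1`, `pathway2`, `macrophage`), and `pairs` (ligand-receptor
#'   pair table).
#' @export
simulate_tam_cells <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n_core <- config$n_cells_core
  n_peri <- config$n_cells_periphery
  n <- n_core + n_peri
  region <- c(rep("core", n_core), rep("periphery", n_peri))
  bt <- config$trajectory_branch_time

  t_lat <- stats::runif(n)
  branch <- ifelse(t_lat < bt, "trunk",
                   ifelse(stats::runif(n) < 0.5, "A", "B"))
  f_ont <- ifelse(region == "core", stats::rbeta(n, 8, 2),
                  stats::rbeta(n, 2, 8))

  # polarization drifts with maturation in a region-dependent direction
  # (pro-inflammatory in core, anti-inflammatory in periphery) and more
  # strongly on branch A than branch B, making the block branch-dependent
  region_sign <- ifelse(region == "core", 1, -1)
  ramp <- pmax(t_lat - bt, 0) / (1 - bt)
  pol <- region_sign * ramp * ifelse(branch == "A", 1,
                                     ifelse(branch == "B", 0.25, 0))
  dif <- 2 * t_lat - 1
  state <- classify_quadrant(dif, pol)
  immature <- state %in% c("M0", "M1-pre")
  proinflam <- state %in% c("M1-pre", "M1-like")

  genes <- synth_gene_programs(config)
  sz <- config$signature_sizes
  # per-cell covariate for each program (rows: program, columns: cells)
  x_prog <- rbind(`ontogeny-BMDM` = 2 * f_ont - 1,
                  `ontogeny-MG` = 1 - 2 * f_ont,
                  polarization = pol,
                  differentiation = dif,
                  ligand = ifelse(immature, 0.5, -0.5),
                  receptor = ifelse(proinflam, 0.5, -0.5),
                  `pathway-1` = ifelse(branch == "A", (t_lat - bt) / (1 - bt), 0),
                  `pathway-2` = as.numeric(branch == "B" & t_lat > 0.8),
                  background = rep(0, n))
  # per-gene signed loading; polarization/differentiation halves get -1
  sgn <- rep(1, config$n_genes)
  half_neg <- function(prog) {
    idx <- which(genes$program == prog)
    sgn[idx[seq(length(idx) / 2 + 1, length(idx))]] <<- -1
  }
  half_neg("polarization")
  half_neg("differentiation")

  w <- exp(config$effect_size * sgn * x_prog[genes$program, , drop = FALSE])
  depth <- config$depth_mean *
    exp(stats::rnorm(n, mean = -0.25^2 / 2, sd = 0.25))
  mu <- sweep(w, 2, depth / colSums(w), `*`)
  counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                  size = 1 / config$nb_dispersion),
                   nrow = config$n_genes,
                   dimnames = list(genes$gene_id,
                                   sprintf("cell%05d", seq_len(n))))

  tumor_id <- paste0("T", (seq_len(n) - 1) %% 4 + 1)
  meta <- data.frame(cell_id = colnames(counts), region = region,
                     tumor_id = tumor_id, stringsAsFactors = FALSE)
  truth_cells <- data.frame(cell_id = colnames(counts),
                            latent_time = t_lat, branch_id = branch,
                            ontogeny_fraction = f_ont,
                            activation_state_true = as.character(state),
                            stringsAsFactors = FALSE)

  gid <- function(prog) genes$gene_id[genes$program == prog]
  pol_g <- gid("polarization"); dif_g <- gid("differentiation")
  signatures <- list(bmdm = gid("ontogeny-BMDM"), mg = gid("ontogeny-MG"),
                     pol_pos = pol_g[seq_len(sz["polarization"] / 2)],
                     pol_neg = pol_g[-seq_len(sz["polarization"] / 2)],
                     dif_pos = dif_g[seq_len(sz["differentiation"] / 2)],
                     dif_neg = dif_g[-seq_len(sz["differentiation"] / 2)],
                     ligands = gid("ligand"), receptors = gid("receptor"),
                     pathway1 = gid("pathway-1"), pathway2 = gid("pathway-2"),
                     macrophage = c(gid("ontogeny-BMDM"), gid("ontogeny-MG")))
  lig <- signatures$ligands; rec <- signatures$receptors
  k <- max(length(lig), length(rec))
  pairs <- unique(data.frame(
    ligand = c(lig[(seq_len(k) - 1) %% length(lig) + 1],
               lig),
    receptor = c(rec[(seq_len(k) - 1) %% length(rec) + 1],
                 rec[(seq_along(lig)) %% length(rec) + 1]),
    stringsAsFactors = FALSE))

  list(counts = tam_counts(counts, meta),
       truth = list(cells = truth_cells, genes = genes),
       signatures = signatures, pairs = pairs)
}

#' Generate synthetic bulk samples as mixtures of single-cell profiles
#'
#' Each bulk sample is the mean count profile of a random subset of cells
#' drawn with region-dependent weights across five anatomic structures:
#' "leading edge" and "infiltrating tumour" samples draw at least
#' `region_weight` of their cells from the periphery, while "cellular
#' tumour", "microvascular proliferation" and "pseudopalisading cells"
#' samples draw the same proportion from the core.
#'
#' @param config the [synth_config] used for the single-cell data (supplies
#'   the seed; bulk sampling uses `seed + 1`).
#' @param sc the [tam_counts] from [simulate_tam_cells].
#' @param truth the matching truth object (unused beyond validation; kept so
#'   callers can thread the full generator output through).
#' @param n_samples_per_region bulk samples per anatomic structure (>= 1).
#' @param n_cells_per_sample cells mixed into each bulk profile (default 100).
#' @param region_weight minimum weight of the structure's dominant region
#'   (default 0.85).
#' @return List with `expr` (genes x samples mean-count matrix) and
#'   `sample_meta` (data.frame: `sample_id`, `structure`).
#' @export
simulate_tam_bulk <- function(config, sc, truth = NULL,
                              n_samples_per_region = 5,
                              n_cells_per_sample = 100,
                              region_weight = 0.85) {
  stopifnot(inherits(config, "synth_config"), inherits(sc, "tam_counts"))
  if (n_samples_per_region < 1) stop("n_samples_per_region must be >= 1")
  stopifnot(region_weight >= 0.8, region_weight <= 1)
  set.seed(config$seed + 1L)
  structures <- c("leading edge", "infiltrating tumour", "cellular tumour",
                  "microvascular proliferation", "pseudopalisading cells")
  peri_dominant <- structures %in% c("leading edge", "infiltrating tumour")
  is_peri <- sc$cell_meta$region == "periphery"
  cmat <- as.matrix(sc$counts)
  profiles <- list(); meta <- list()
  for (si in seq_along(structures)) {
    w <- ifelse(is_peri == peri_dominant[si],
                region_weight / max(1, sum(is_peri == peri_dominant[si])),
                (1 - region_weight) / max(1, sum(is_peri != peri_dominant[si])))
    for (j in seq_len(n_samples_per_region)) {
      idx <- sample.int(ncol(cmat), n_cells_per_sample, replace = TRUE,
                        prob = w)
      id <- sprintf("bulk_%02d_%02d", si, j)
      profiles[[id]] <- rowMeans(cmat[, idx, drop = FALSE])
      meta[[id]] <- data.frame(sample_id = id, structure = structures[si],
                               stringsAsFactors = FALSE)
    }
  }
  expr <- do.call(cbind, profiles)
  rownames(expr) <- rownames(cmat)
  list(expr = expr, sample_meta = do.call(rbind, c(meta, make.row.names = FALSE)))
}

#' Write a simulated dataset to disk in standard formats
#'
#' Writes MatrixMarket counts (`matrix.mtx`, 1-based coordinate) with
#' `genes.tsv` / `cells.tsv` sidecars, the cell and gene truth tables as TSV,
#' the signatures as GMT and the ligand-receptor pairs as TSV.
#'
#' @param sim output of [simulate_tam_cells].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_tam_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(sim$counts$counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(sim$counts$counts), file.path(dir, "genes.tsv"))
  utils::write.table(sim$counts$cell_meta, file.path(dir, "cells.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$cells, file.path(dir, "truth_cells.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$genes, file.path(dir, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_gmt(sim$signatures, file.path(dir, "signatures.gmt"))
  utils::write.table(sim$pairs, file.path(dir, "pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
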