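#' Default stage x cell-type presence grid
#'
#' The 21-identity presence pattern of cranial ectoderm over neurulation: an
#' undecided pan-ectodermal population at the three earliest stages only, the
#' neural plate border at the 4-somite stage, neural crest from the 7-somite
#' stage onward, and non-neural ectoderm plus dorsal and ventral neural
#' domains at all five stages. Exercises every grid code path (cell types
#' absent at some stages) by construction.
#'
#' @return Data.frame with columns `stage` and `cell_type` (21 rows).
#' @export
default_presence_grid <- function() {
  stages <- default_stage_order()
  rbind(
    expand.grid(stage = stages[1:3], cell_type = "undecided",
                stringsAsFactors = FALSE),
    data.frame(stage = "HH8_4som", cell_type = "neural_plate_border",
               stringsAsFactors = FALSE),
    expand.grid(stage = stages[4:5], cell_type = "neural_crest",
                stringsAsFactors = FALSE),
    expand.grid(stage = stages,
                cell_type = c("non_neural_ectoderm", "dorsal_neural",
                              "ventral_neural"),
                stringsAsFactors = FALSE)
  )
}

#' Built-in toy ligand-receptor pair table
#'
#' Five pathways (WNT, BMP, FGF, TGFb, HH), one single-subunit and, for WNT,
#' one two-subunit receptor pair, over dedicated synthetic ligand/receptor
#' gene symbols.
#'
#' @return A [lr_pairs()] table.
#' @export
default_lr_pairs <- function() {
  lr_pairs(data.frame(
    ligand = c("WntL1", "WntL2", "BmpL1", "FgfL1", "TgfbL1", "HhL1"),
    receptor = c("WntR1A;WntR1B", "WntR2", "BmpR1", "FgfR1", "TgfbR1", "HhR1"),
    pathway = c("WNT", "WNT", "BMP", "FGF", "TGFb", "HH"),
    stringsAsFactors = FALSE
  ))
}

#' Simulation configuration
#'
#' Defines the synthetic study: a negative-binomial count model over the
#' stage x cell-type presence grid, signed regulons with planted activation
#' or repression in chosen identities, planted ligand-receptor
#' source/receiver pairs, and ATAC read-table parameters. The same config
#' and seed always produce identical outputs.
#'
#' Count model: per-gene baseline means are log-normal around
#' `baseline_mean`, per-cell library factors log-normal with
#' `library_sdlog`, and counts negative binomial with shared `dispersion`
#' (variance `mu + dispersion * mu^2`). A planted (tf, identity, direction)
#' shifts each target's log-mean in that identity by
#' `effect_size * edge_weight * direction`. Ligand / receptor genes sit at
#' the low `lr_base_mean` baseline and are raised `lr_fold`-fold in their
#' planted source / target identity.
#'
#' @param n_genes Target-pool gene count (regulon targets are drawn here).
#' @param n_tfs Number of TF genes (added on top of `n_genes`).
#' @param targets_per_tf Regulon size.
#' @param cells_per_identity Cells simulated per identity.
#' @param presence_grid Data.frame of (stage, cell_type) rows.
#' @param stage_order Ordered stage set.
#' @param planted_activity `NULL` (default: `n_planted` activations on
#'   distinct TFs in distinct identities, drawn from the seed) or a
#'   data.frame with columns `tf`, `identity`, `direction`
#'   (`"activated"` / `"repressed"`).
#' @param n_planted Number of default planted activations (default 10).
#' @param effect_size Natural-log shift applied to target means
#'   (default 1.5).
#' @param program_genes_per_identity Size of each identity's own marker
#'   program: genes (disjoint from all regulons and across identities)
#'   elevated in exactly that identity, emulating the cell-type signatures
#'   real identities carry (default 20).
#' @param program_effect_size Natural-log elevation of program genes
#'   (default 1.5).
#' @param baseline_mean Median baseline counts per gene per cell
#'   (default 5).
#' @param mean_sdlog Log-normal spread of per-gene baselines (default 0.4).
#' @param dispersion Shared negative-binomial dispersion (default 0.05).
#' @param library_sdlog Log-normal spread of per-cell library factors.
#' @param repressor_fraction Fraction of regulon edges with weight -1.
#' @param lr_pairs Ligand-receptor table (default [default_lr_pairs()]).
#' @param lr_planted `NULL` (default: one planted pair between two
#'   seed-drawn identities) or a data.frame with columns `pair`, `source`,
#'   `target`, `fold`.
#' @param lr_base_mean Baseline mean counts of ligand/receptor genes.
#' @param lr_fold Elevation fold for planted ligand/receptor genes.
#' @param atac_lambda Mean motif occurrences per TF (Poisson).
#' @param atac_read_mean Mean reads per occurrence (negative binomial).
#' @param atac_read_dispersion Dispersion of per-occurrence reads.
#' @param atac_shift Read-mean multiplier for the positive group when
#'   [generate_atac()] is run with `same_distribution = FALSE`.
#' @param seed Integer seed.
#' @return A `SimulationConfig` list.
#' @export
simulation_config <- function(n_genes = 2000, n_tfs = 50, targets_per_tf = 20,
                              cells_per_identity = 100,
                              presence_grid = default_presence_grid(),
                              stage_order = default_stage_order(),
                              planted_activity = NULL, n_planted = 10,
                              effect_size = 1.5,
                              program_genes_per_identity = 20,
                              program_effect_size = 1.5,
                              baseline_mean = 5, mean_sdlog = 0.4,
                              dispersion = 0.05, library_sdlog = 0.2,
                              repressor_fraction = 0.2,
                              lr_pairs = default_lr_pairs(),
                              lr_planted = NULL,
                              lr_base_mean = 0.02, lr_fold = 100,
                              atac_lambda = 100, atac_read_mean = 30,
                              atac_read_dispersion = 1, atac_shift = 2,
                              seed = 1) {
  stopifnot(n_genes > 0, n_tfs > 0, targets_per_tf > 0,
            cells_per_identity > 0, effect_size >= 0, baseline_mean > 0,
            dispersion > 0)
  if (n_tfs * targets_per_tf +
      nrow(presence_grid) * program_genes_per_identity > n_genes) {
    stop("gene pool too small for disjoint regulons and identity programs")
  }
  cfg <- list(
    n_genes = n_genes, n_tfs = n_tfs, targets_per_tf = targets_per_tf,
    cells_per_identity = cells_per_identity,
    presence_grid = presence_grid, stage_order = stage_order,
    planted_activity = planted_activity, n_planted = n_planted,
    effect_size = effect_size,
    program_genes_per_identity = program_genes_per_identity,
    program_effect_size = program_effect_size,
    baseline_mean = baseline_mean,
    mean_sdlog = mean_sdlog, dispersion = dispersion,
    library_sdlog = library_sdlog,
    repressor_fraction = repressor_fraction,
    lr_pairs = lr_pairs, lr_planted = lr_planted,
    lr_base_mean = lr_base_mean, lr_fold = lr_fold,
    atac_lambda = atac_lambda, atac_read_mean = atac_read_mean,
    atac_read_dispersion = atac_read_dispersion, atac_shift = atac_shift,
    seed = seed
  )
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Generate a synthetic expression bundle with planted regulatory truth
#'
#' Draws disjoint signed regulons, simulates negative-binomial counts over
#' the configured presence grid, plants activation / repression shifts on
#' regulon targets and ligand-receptor elevation in source / receiver
#' identities, and records the planted truth. Deterministic given the
#' config (which carries the seed).
#'
#' @param config A [simulation_config()].
#' @return List with `matrix` (`ExpressionMatrix`, counts only), `annot`
#'   (cell annotations), `network` ([regulon_network()]), `pairs` (the
#'   ligand-receptor table) and `truth` (list with `planted_activity` and
#'   `lr_planted`).
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  grid_df <- config$presence_grid
  identities <- identity_label(grid_df$stage, grid_df$cell_type)
  n_id <- length(identities)

  pool <- sprintf("G%04d", seq_len(config$n_genes))
  tfs <- sprintf("TF%02d", seq_len(config$n_tfs))
  lr_genes <- unique(c(config$lr_pairs$ligand,
                       unlist(config$lr_pairs$subunits)))
  genes <- c(pool, tfs, lr_genes)

  # disjoint regulons keep every planted signal attributable to one TF
  perm <- sample(pool)
  edges <- data.frame(
    source = rep(tfs, each = config$targets_per_tf),
    target = perm[seq_len(config$n_tfs * config$targets_per_tf)],
    stringsAsFactors = FALSE
  )
  edges$weight <- ifelse(
    stats::runif(nrow(edges)) < config$repressor_fraction, -1, 1)
  network <- regulon_network(edges)

  # each identity's own marker program, disjoint from every regulon
  n_reg <- config$n_tfs * config$targets_per_tf
  program <- split(
    perm[n_reg + seq_len(n_id * config$program_genes_per_identity)],
    rep(identities, each = config$program_genes_per_identity)
  )

  planted <- config$planted_activity
  if (is.null(planted)) {
    if (config$n_planted > min(config$n_tfs, n_id)) {
      stop("n_planted exceeds available TFs or identities")
    }
    planted <- data.frame(
      tf = tfs[seq_len(config$n_planted)],
      identity = sample(identities, config$n_planted),
      direction = "activated",
      stringsAsFactors = FALSE
    )
  }
  if (!all(planted$tf %in% tfs)) stop("planted TF not in the network")
  if (!all(planted$identity %in% identities)) {
    stop("planted identity not in the presence grid")
  }
  if (!all(planted$direction %in% c("activated", "repressed"))) {
    stop("planted direction must be 'activated' or 'repressed'")
  }

  lr_planted <- config$lr_planted
  if (is.null(lr_planted)) {
    st <- sample(identities, 2)
    lr_planted <- data.frame(pair = config$lr_pairs$pair[1],
                             source = st[1], target = st[2],
                             fold = config$lr_fold,
                             stringsAsFactors = FALSE)
  }
  if (!all(lr_planted$pair %in% config$lr_pairs$pair)) {
    stop("planted pair not in the pair table")
  }

  # genes x identities natural-log shifts
  shift <- matrix(0, nrow = length(genes), ncol = n_id,
                  dimnames = list(genes, identities))
  for (i in seq_len(nrow(planted))) {
    e <- edges[edges$source == planted$tf[i], ]
    if (!nrow(e)) stop("planted TF without targets: ", planted$tf[i])
    dir <- if (planted$direction[i] == "activated") 1 else -1
    shift[e$target, planted$identity[i]] <-
      shift[e$target, planted$identity[i]] +
      config$effect_size * e$weight * dir
  }
  for (id in names(program)) {
    shift[program[[id]], id] <- shift[program[[id]], id] +
      config$program_effect_size
  }
  for (i in seq_len(nrow(lr_planted))) {
    k <- match(lr_planted$pair[i], config$lr_pairs$pair)
    lig <- config$lr_pairs$ligand[k]
    sub <- config$lr_pairs$subunits[[k]]
    shift[lig, lr_planted$source[i]] <-
      shift[lig, lr_planted$source[i]] + log(lr_planted$fold[i])
    shift[sub, lr_planted$target[i]] <-
      shift[sub, lr_planted$target[i]] + log(lr_planted$fold[i])
  }

  base <- config$baseline_mean *
    exp(stats::rnorm(length(genes), 0, config$mean_sdlog))
  names(base) <- genes
  base[lr_genes] <- config$lr_base_mean

  n_cells <- n_id * config$cells_per_identity
  cell_identity <- rep(identities, each = config$cells_per_identity)
  lib <- exp(stats::rnorm(n_cells, 0, config$library_sdlog))
  mu <- (base * exp(shift[, match(cell_identity, identities)])) *
    rep(lib, each = length(genes))
  counts <- matrix(
    stats::rnbinom(length(mu), mu = as.vector(mu), size = 1 / config$dispersion),
    nrow = length(genes),
    dimnames = list(genes, sprintf("cell%05d", seq_len(n_cells)))
  )
  counts <- Matrix::Matrix(counts, sparse = TRUE)

  idx <- match(cell_identity, identities)
  annot <- data.frame(
    cell_id = colnames(counts),
    stage = grid_df$stage[idx], cell_type = grid_df$cell_type[idx],
    mito_fraction = stats::runif(n_cells, 0, 0.003),
    n_genes_detected = as.integer(Matrix::colSums(counts > 0)),
    stringsAsFactors = FALSE, row.names = NULL
  )

  list(
    matrix = expression_matrix(counts),
    annot = annot,
    network = network,
    pairs = config$lr_pairs,
    truth = list(planted_activity = planted, lr_planted = lr_planted)
  )
}

#' Generate synthetic ATAC motif-occurrence read tables
#'
#' Per TF, an occurrence count drawn Poisson(`atac_lambda`) and
#' negative-binomial reads per occurrence; occurrences are placed at random
#' positions on a toy three-chromosome genome. With
#' `same_distribution = TRUE` (the null scenario) both activity-sign groups
#' share all parameters; otherwise the positive group's read means are
#' multiplied by `atac_shift`.
#'
#' @param config A [simulation_config()] (ATAC parameters and seed).
#' @param positive_tfs,negative_tfs Disjoint character vectors of TF names.
#' @param same_distribution Logical (default TRUE).
#' @param seed Optional seed overriding `config$seed`.
#' @return List with `table` (data.frame `tf`, `chrom`, `start`, `end`,
#'   `read_count`) and `truth` (group assignment and scenario).
#' @export
generate_atac <- function(config, positive_tfs, negative_tfs,
                          same_distribution = TRUE, seed = config$seed) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (length(intersect(positive_tfs, negative_tfs))) {
    stop("TF groups must be disjoint")
  }
  set.seed(seed)
  all_tfs <- c(positive_tfs, negative_tfs)
  rows <- lapply(all_tfs, function(tf) {
    n <- stats::rpois(1, config$atac_lambda)
    if (n == 0) return(NULL)
    m <- config$atac_read_mean
    if (!same_distribution && tf %in% positive_tfs) m <- m * config$atac_shift
    start <- sample.int(1e6, n)
    data.frame(
      tf = tf,
      chrom = sample(c("chr1", "chr2", "chr3"), n, replace = TRUE),
      start = start, end = start + 10L,
      read_count = stats::rnbinom(n, mu = m,
                                  size = 1 / config$atac_read_dispersion),
      stringsAsFactors = FALSE
    )
  })
  table <- do.call(rbind, rows)
  if (is.null(table)) {
    table <- data.frame(tf = character(), chrom = character(),
                        start = integer(), end = integer(),
                        read_count = integer(), stringsAsFactors = FALSE)
  }
  rownames(table) <- NULL
  list(table = table,
       truth = list(positive_tfs = positive_tfs,
                    negative_tfs = negative_tfs,
                    same_distribution = same_distribution))
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  cfg <- config
  cfg$lr_pairs <- cfg$lr_pairs[c("ligand", "receptor", "pathway")]
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Write a generated bundle to disk
#'
#' Lays out a directory every pipeline reader understands: MatrixMarket
#' counts with TSV sidecars, the annotation, regulon and ligand-receptor
#' tables, the ATAC occurrence table as GFF3 plus a read-count TSV, the
#' ground truth as JSON, and -- written last, so a partial bundle is
#' detectable by its absence -- a manifest with the config hash and seed.
#'
#' @param outputs Result of [generate_expression()], optionally with an
#'   `atac` element from [generate_atac()] and a `config` element.
#' @param directory Output directory (created if needed).
#' @param config The [simulation_config()] used (for the manifest).
#' @return The manifest list, invisibly.
#' @export
write_bundle <- function(outputs, directory, config = outputs$config) {
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  write_expression_mtx(outputs$matrix, directory)
  write_cell_annotations(outputs$annot,
                         file.path(directory, "annotations.tsv"))
  write_regulon_network(outputs$network, file.path(directory, "regulons.tsv"))
  utils::write.table(outputs$pairs[c("ligand", "receptor", "pathway")],
                     file.path(directory, "lr_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(outputs$atac)) {
    tab <- outputs$atac$table
    utils::write.table(tab, file.path(directory, "motif_reads.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    gr <- GenomicRanges::GRanges(
      tab$chrom, IRanges::IRanges(tab$start + 1L, tab$end),
      motif_id = tab$tf, score = tab$read_count
    )
    rtracklayer::export(gr, file.path(directory, "motifs.gff3"),
                        format = "GFF3")
  }
  truth <- outputs$truth
  if (!is.null(outputs$atac)) truth$atac <- outputs$atac$truth
  jsonlite::write_json(truth, file.path(directory, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  manifest <- list(
    config_hash = if (is.null(config)) NA_character_ else config_hash(config),
    seed = if (is.null(config)) NA_integer_ else config$seed,
    files = list.files(directory)
  )
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}

#' Read a bundle written by [write_bundle()]
#'
#' @param directory Bundle directory; an absent manifest means the bundle is
#'   incomplete and is an error.
#' @return List with `matrix`, `annot`, `network`, `pairs`, `truth`,
#'   `manifest`, and `atac` when present.
#' @export
read_bundle <- function(directory) {
  manifest_path <- file.path(directory, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop("no manifest.json: incomplete or foreign bundle")
  }
  out <- list(
    matrix = read_expression_mtx(directory),
    annot = read_cell_annotations(file.path(directory, "annotations.tsv")),
    network = read_regulon_network(file.path(directory, "regulons.tsv")),
    pairs = read_lr_pairs(file.path(directory, "lr_pairs.tsv")),
    truth = jsonlite::read_json(file.path(directory, "ground_truth.json"),
                                simplifyVector = TRUE),
    manifest = jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  )
  reads_path <- file.path(directory, "motif_reads.tsv")
  if (file.exists(reads_path)) {
    out$atac <- list(table = utils::read.delim(reads_path,
                                               stringsAsFactors = FALSE))
  }
  out
}
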