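# Synthetic paired-species atlas generator with ground-truth homology,
# cell-type correspondence, and planted paralog substitutions.

#' Configuration for the paired-species simulator
#'
#' Defaults describe a pair of desk-scale embryo-like atlases: 8 cell
#' types of 150 cells each, 1200 ortholog groups, 40-gene expression
#' programs per type, negative-binomial counts with lognormal library
#' sizes and independent dropout.
#'
#' @param n_celltypes Cell types per species.
#' @param cells_per_type Cells per type.
#' @param n_ortholog_groups Ortholog groups shared by the two species.
#' @param frac_one_to_many Fraction of groups with two copies in
#'   species 2 (one-to-many homology).
#' @param frac_many_to_many Fraction of groups with two copies in both
#'   species.
#' @param frac_species_specific Fraction of each species' transcriptome
#'   without cross-species homology.
#' @param frac_paralog_families Fraction of ortholog groups paired into
#'   ancient paralog families.
#' @param program_size Marker genes per cell-type program.
#' @param divergence Fraction of each program swapped to unrelated genes
#'   in species 2.
#' @param n_substitutions Planted paralog-substitution events.
#' @param mean_high,mean_low NB mean expression for program / background
#'   genes.
#' @param dispersion NB size parameter.
#' @param dropout Independent zero-inflation probability.
#' @param size_factor_sd Lognormal sd of per-cell library size factors.
#' @param decoy_frac Fraction of genes receiving a one-directional decoy
#'   BLAST hit.
#' @param seed Random seed; all outputs are deterministic given it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_celltypes = 8, cells_per_type = 150,
                       n_ortholog_groups = 1200, frac_one_to_many = 0,
                       frac_many_to_many = 0, frac_species_specific = 0,
                       frac_paralog_families = 0.4, program_size = 40,
                       divergence = 0, n_substitutions = 0,
                       mean_high = 8, mean_low = 0.2, dispersion = 2,
                       dropout = 0.1, size_factor_sd = 0.3,
                       decoy_frac = 0.05, seed = 1) {
  cfg <- as.list(environment())
  fr <- c(frac_one_to_many, frac_many_to_many, frac_species_specific,
          frac_paralog_families, divergence, dropout, decoy_frac)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (any(c(n_celltypes, cells_per_type, n_ortholog_groups,
            program_size) <= 0)) stop("counts must be positive")
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic species pair with ground truth
#'
#' Emits two expression atlases whose cell types share homologous gene
#' programs (up to the configured divergence and species-specific
#' signal), reciprocal BLAST-like tables with bit scores proportional to
#' simulated sequence identity (plus one-directional decoy hits), an
#' orthology-group table spanning a recent (ortholog) and an ancestral
#' (paralog-family) level, and a ground-truth record of homology
#' relations, cell-type correspondences and planted substitutions.
#' Planted substitutions silence an ortholog in species 2 and hand its
#' expression program to an ancient paralog.
#'
#' @param config A [sim_config()].
#' @return A list with `atlas_1`, `atlas_2` (`expression_atlas`),
#'   `blast_12`, `blast_21` (12-column BLAST-like data.frames),
#'   `orthology` (gene_id, level, group_id), `truth` and `config`.
#' @export
generate_species_pair <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  G <- config$n_ortholog_groups
  Tn <- config$n_celltypes
  ps <- config$program_size

  # --- homology structure ---------------------------------------------
  copies1 <- rep(1L, G); copies2 <- rep(1L, G)
  n_o2m <- round(config$frac_one_to_many * G)
  n_m2m <- round(config$frac_many_to_many * G)
  multi <- sample.int(G, n_o2m + n_m2m)
  if (n_o2m) copies2[multi[seq_len(n_o2m)]] <- 2L
  if (n_m2m) {
    idx <- multi[n_o2m + seq_len(n_m2m)]
    copies1[idx] <- 2L; copies2[idx] <- 2L
  }
  group_genes <- function(g, copies) {
    if (copies[g] == 1) paste0("og", g) else paste0("og", g, c("", "b"))
  }
  genes1 <- unlist(lapply(seq_len(G), group_genes, copies = copies1))
  genes2 <- unlist(lapply(seq_len(G), group_genes, copies = copies2))
  gene_group1 <- rep(seq_len(G), copies1)
  gene_group2 <- rep(seq_len(G), copies2)

  n_fam <- floor(config$frac_paralog_families * G / 2)
  fam_of <- rep(NA_integer_, G)
  ancient_levels <- c("Chordata", "Bilateria", "Metazoa", "Opisthokonta",
                      "Eukaryota")
  fam_age <- character(0)
  if (n_fam > 0) {
    fam_members <- matrix(sample.int(G, 2 * n_fam), ncol = 2)
    fam_of[fam_members[, 1]] <- seq_len(n_fam)
    fam_of[fam_members[, 2]] <- seq_len(n_fam)
    fam_age <- sample(ancient_levels, n_fam, replace = TRUE)
  }

  # species-specific genes (no homology edge)
  n_spec1 <- round(length(genes1) * config$frac_species_specific /
                     max(1 - config$frac_species_specific, 1e-9))
  n_spec2 <- round(length(genes2) * config$frac_species_specific /
                     max(1 - config$frac_species_specific, 1e-9))
  spec1 <- if (n_spec1) paste0("s1spec", seq_len(n_spec1)) else character(0)
  spec2 <- if (n_spec2) paste0("s2spec", seq_len(n_spec2)) else character(0)
  all_genes1 <- c(genes1, spec1)
  all_genes2 <- c(genes2, spec2)

  # --- cell-type programs ---------------------------------------------
  if (Tn * ps > G) stop("programs larger than gene pool: need ",
                        Tn * ps, " groups, have ", G)
  prog_groups <- split(sample.int(G, Tn * ps),
                       rep(seq_len(Tn), each = ps))
  used <- unlist(prog_groups)
  free_groups <- setdiff(seq_len(G), used)

  nd <- round(config$divergence * ps)
  if (Tn * nd > length(free_groups))
    stop("not enough free groups for the requested divergence")
  prog2_groups <- prog_groups
  repl_pool <- sample(free_groups)
  ri <- 0L
  for (t in seq_len(Tn)) {
    if (nd == 0) break
    drop_idx <- sample.int(ps, nd)
    repl <- repl_pool[ri + seq_len(nd)]; ri <- ri + nd
    prog2_groups[[t]] <- c(prog_groups[[t]][-drop_idx], repl)
  }
  used2 <- unlist(prog2_groups)

  # --- planted substitutions ------------------------------------------
  silenced2 <- character(0)
  truth_sub <- data.frame(cell_type = character(0), gene = character(0),
                          ortholog_gene = character(0),
                          substituted_by = character(0),
                          stringsAsFactors = FALSE)
  if (config$n_substitutions > 0) {
    eligible <- list()
    for (t in seq_len(Tn)) {
      shared <- intersect(prog_groups[[t]], prog2_groups[[t]])
      for (g in shared) {
        f <- fam_of[g]
        if (is.na(f)) next
        partner <- setdiff(which(!is.na(fam_of) & fam_of == f), g)
        if (!length(partner)) next
        h <- partner[1]
        if (h %in% used || h %in% used2) next
        if (copies2[g] != 1 || copies2[h] != 1) next
        eligible[[length(eligible) + 1L]] <- c(t = t, g = g, h = h)
      }
    }
    if (length(eligible) < config$n_substitutions)
      stop("only ", length(eligible),
           " groups eligible for substitution planting; requested ",
           config$n_substitutions)
    elig <- do.call(rbind, eligible)
    elig <- elig[!duplicated(elig[, "g"]) & !duplicated(elig[, "h"]), ,
                 drop = FALSE]
    pick <- elig[sample.int(nrow(elig), config$n_substitutions), ,
                 drop = FALSE]
    for (r in seq_len(nrow(pick))) {
      t <- pick[r, "t"]; g <- pick[r, "g"]; h <- pick[r, "h"]
      prog2_groups[[t]] <- c(setdiff(prog2_groups[[t]], g), h)
      silenced2 <- c(silenced2, paste0("og", g))
      truth_sub <- rbind(truth_sub, data.frame(
        cell_type = paste0("T", t),
        gene = paste0("sp1_og", g),
        ortholog_gene = paste0("sp2_og", g),
        substituted_by = paste0("sp2_og", h),
        stringsAsFactors = FALSE))
    }
  }

  # program gene sets per species (all copies of the member groups,
  # plus species-specific genes attached to random types)
  prog_genes <- function(groups, gene_group, genes) {
    genes[gene_group %in% groups]
  }
  programs1 <- lapply(prog_groups, prog_genes, gene_group1, genes1)
  programs2 <- lapply(prog2_groups, prog_genes, gene_group2, genes2)
  assign_spec <- function(spec, programs) {
    for (sg in spec) {
      if (stats::runif(1) < 0.5) {
        t <- sample.int(Tn, 1)
        programs[[t]] <- c(programs[[t]], sg)
      }
    }
    programs
  }
  programs1 <- assign_spec(spec1, programs1)
  programs2 <- assign_spec(spec2, programs2)

  # --- counts ----------------------------------------------------------
  make_counts <- function(all_genes, programs, silenced) {
    m <- length(all_genes)
    n <- Tn * config$cells_per_type
    type_of <- rep(seq_len(Tn), each = config$cells_per_type)
    mu_type <- matrix(config$mean_low, Tn, m,
                      dimnames = list(NULL, all_genes))
    for (t in seq_len(Tn)) mu_type[t, programs[[t]]] <- config$mean_high
    if (length(silenced)) mu_type[, silenced] <- 0.01
    sf <- stats::rlnorm(n, 0, config$size_factor_sd)
    mu <- mu_type[type_of, , drop = FALSE] * sf
    counts <- matrix(stats::rnbinom(n * m, size = config$dispersion,
                                    mu = as.vector(mu)), n, m)
    if (config$dropout > 0) {
      keep <- matrix(stats::rbinom(n * m, 1, 1 - config$dropout), n, m)
      counts <- counts * keep
    }
    dimnames(counts) <- list(sprintf("cell%04d", seq_len(n)), all_genes)
    list(counts = counts, cell_types = paste0("T", type_of))
  }
  d1 <- make_counts(all_genes1, programs1, character(0))
  d2 <- make_counts(all_genes2, programs2, silenced2)
  atlas_1 <- expression_atlas(d1$counts, all_genes1,
                              rownames(d1$counts), "sp1", d1$cell_types)
  atlas_2 <- expression_atlas(d2$counts, all_genes2,
                              rownames(d2$counts), "sp2", d2$cell_types)

  # --- BLAST-like tables ----------------------------------------------
  .bit <- function(identity) pmax(30, 200 * identity +
                                    stats::rnorm(length(identity), 0, 10))
  .rows <- function(q, s, identity) {
    if (!length(q)) return(NULL)
    bit <- .bit(identity)
    data.frame(qseqid = q, sseqid = s, pident = round(identity * 100, 1),
               length = 200L, mismatch = 0L, gapopen = 0L, qstart = 1L,
               qend = 200L, sstart = 1L, send = 200L,
               evalue = 10^(-bit / 2), bitscore = round(bit, 1),
               stringsAsFactors = FALSE)
  }
  orth_q <- character(0); orth_s <- character(0)
  for (g in seq_len(G)) {
    gs1 <- group_genes(g, copies1); gs2 <- group_genes(g, copies2)
    pr <- expand.grid(q = gs1, s = gs2, stringsAsFactors = FALSE)
    orth_q <- c(orth_q, pr$q); orth_s <- c(orth_s, pr$s)
  }
  par_q <- character(0); par_s <- character(0)
  if (n_fam > 0) for (f in seq_len(n_fam)) {
    gs <- which(!is.na(fam_of) & fam_of == f)
    if (length(gs) < 2) next
    g <- gs[1]; h <- gs[2]
    pr <- rbind(
      expand.grid(q = group_genes(g, copies1), s = group_genes(h, copies2),
                  stringsAsFactors = FALSE),
      expand.grid(q = group_genes(h, copies1), s = group_genes(g, copies2),
                  stringsAsFactors = FALSE))
    par_q <- c(par_q, pr$q); par_s <- c(par_s, pr$s)
  }
  id_orth <- pmin(0.98, pmax(0.6, stats::rnorm(length(orth_q), 0.85, 0.05)))
  id_par <- pmin(0.7, pmax(0.4, stats::rnorm(length(par_q), 0.55, 0.05)))
  blast_12 <- rbind(.rows(orth_q, orth_s, id_orth),
                    .rows(par_q, par_s, id_par))
  blast_21 <- rbind(.rows(orth_s, orth_q,
                          pmin(0.98, pmax(0.6, id_orth +
                                            stats::rnorm(length(id_orth), 0, 0.02)))),
                    .rows(par_s, par_q,
                          pmin(0.7, pmax(0.4, id_par +
                                           stats::rnorm(length(id_par), 0, 0.02)))))
  n_decoy <- round(config$decoy_frac * length(all_genes1))
  if (n_decoy > 0) {
    dq <- sample(all_genes1, n_decoy, replace = TRUE)
    ds <- sample(all_genes2, n_decoy, replace = TRUE)
    hom_key <- paste(rep(seq_len(G), copies1)[match(dq, genes1)],
                     rep(seq_len(G), copies2)[match(ds, genes2)])
    keep <- is.na(match(dq, genes1)) | is.na(match(ds, genes2)) |
      rep(seq_len(G), copies1)[match(dq, genes1)] !=
      rep(seq_len(G), copies2)[match(ds, genes2)]
    dq <- dq[keep]; ds <- ds[keep]
    if (length(dq)) {
      half <- seq_along(dq) %% 2 == 0
      id_d <- pmin(0.6, pmax(0.35, stats::rnorm(length(dq), 0.45, 0.05)))
      blast_12 <- rbind(blast_12, .rows(dq[!half], ds[!half], id_d[!half]))
      blast_21 <- rbind(blast_21, .rows(ds[half], dq[half], id_d[half]))
    }
  }

  # --- orthology table and truth --------------------------------------
  orth_tab <- rbind(
    data.frame(gene_id = paste0("sp1_", genes1), level = "Vertebrata",
               group_id = paste0("OG", gene_group1),
               stringsAsFactors = FALSE),
    data.frame(gene_id = paste0("sp2_", genes2), level = "Vertebrata",
               group_id = paste0("OG", gene_group2),
               stringsAsFactors = FALSE))
  if (n_fam > 0) {
    f1 <- fam_of[gene_group1]; f2 <- fam_of[gene_group2]
    orth_tab <- rbind(
      orth_tab,
      data.frame(gene_id = paste0("sp1_", genes1[!is.na(f1)]),
                 level = fam_age[f1[!is.na(f1)]],
                 group_id = paste0("FAM", f1[!is.na(f1)]),
                 stringsAsFactors = FALSE),
      data.frame(gene_id = paste0("sp2_", genes2[!is.na(f2)]),
                 level = fam_age[f2[!is.na(f2)]],
                 group_id = paste0("FAM", f2[!is.na(f2)]),
                 stringsAsFactors = FALSE))
  }
  hom_pairs <- rbind(
    data.frame(gene_1 = paste0("sp1_", orth_q),
               gene_2 = paste0("sp2_", orth_s),
               relation = "ortholog", stringsAsFactors = FALSE),
    if (length(par_q))
      data.frame(gene_1 = paste0("sp1_", par_q),
                 gene_2 = paste0("sp2_", par_s),
                 relation = "paralog", stringsAsFactors = FALSE))
  truth <- list(
    homology_pairs = hom_pairs,
    celltype_pairs = data.frame(type_1 = paste0("T", seq_len(Tn)),
                                type_2 = paste0("T", seq_len(Tn)),
                                stringsAsFactors = FALSE),
    substitutions = truth_sub,
    programs = list(sp1 = programs1, sp2 = programs2),
    silenced_sp2 = silenced2
  )
  list(atlas_1 = atlas_1, atlas_2 = atlas_2, blast_12 = blast_12,
       blast_21 = blast_21, orthology = orth_tab, truth = truth,
       config = config)
}
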