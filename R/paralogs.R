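# Ortholog/paralog classification of homologous gene pairs and
# paralog-substitution detection.

#' Default taxonomic level ordering, most recent first
#' @export
DEFAULT_LEVELS <- c("Vertebrata", "Chordata", "Bilateria", "Metazoa",
                    "Opisthokonta", "Eukaryota")

#' Classify homologous gene pairs as orthologs or paralogs
#'
#' A pair sharing an orthology group at the two species' most recent
#' common ancestor level is an ortholog; a pair whose most recent shared
#' group is strictly more ancestral is a paralog; a linked pair sharing
#' no group at any level is unannotated.
#'
#' @param pairs Data.frame with columns `gene_a`, `gene_b` and
#'   optionally `r` (expression correlation).
#' @param orthology_table Data.frame with columns `gene_id`, `level`,
#'   `group_id`.
#' @param mrca_level The taxonomic level of the species pair's most
#'   recent common ancestor (default the most recent level in
#'   `level_order`).
#' @param level_order Taxonomic levels ordered most recent to most
#'   ancestral (default [DEFAULT_LEVELS]); levels absent from the table
#'   are simply never shared.
#' @return Data.frame of class `homolog_classification` with `relation`
#'   (`ortholog` / `paralog` / `unannotated`) and `age_level` (most
#'   recent shared level, NA if unannotated) columns appended.
#' @export
classify_pairs <- function(pairs, orthology_table,
                           mrca_level = level_order[1],
                           level_order = DEFAULT_LEVELS) {
  if (!mrca_level %in% level_order)
    stop("mrca_level must be one of level_order")
  mrca_idx <- match(mrca_level, level_order)
  key <- function(gene, level) paste(gene, level, sep = "\r")
  lut <- stats::setNames(as.character(orthology_table$group_id),
                         key(orthology_table$gene_id,
                             orthology_table$level))
  n <- nrow(pairs)
  age_idx <- rep(NA_integer_, n)
  for (li in seq_along(level_order)) {
    lv <- level_order[li]
    ga <- lut[key(pairs$gene_a, lv)]
    gb <- lut[key(pairs$gene_b, lv)]
    shared <- !is.na(ga) & !is.na(gb) & ga == gb
    age_idx[is.na(age_idx) & shared] <- li
  }
  relation <- ifelse(is.na(age_idx), "unannotated",
                     ifelse(age_idx <= mrca_idx, "ortholog", "paralog"))
  pairs$relation <- relation
  pairs$age_level <- ifelse(is.na(age_idx), NA_character_,
                            level_order[age_idx])
  class(pairs) <- c("homolog_classification", "data.frame")
  pairs
}

#' Detect paralog substitutions from classified pair correlations
#'
#' For every gene with at least one correlated paralog, compares its
#' best paralog correlation against its best ortholog correlation
#' (treated as 0 when no ortholog is scored, flagging the ortholog as
#' absent or lowly expressed). When the difference exceeds
#' `diff_threshold` (strict `>`), the ortholog is considered substituted
#' by the paralog; every paralog exceeding the threshold is listed, with
#' the best-correlated one flagged.
#'
#' @param classified Output of [classify_pairs()] including an `r`
#'   column.
#' @param diff_threshold Minimum correlation difference (default 0.3).
#' @return A `substitution_events` data.frame with columns `gene`,
#'   `ortholog_gene`, `substituted_by`, `corr_paralog`, `corr_ortholog`,
#'   `diff`, `age_level`, `best`, `ortholog_absent`.
#' @export
detect_substitutions <- function(classified, diff_threshold = 0.3) {
  stopifnot(!is.null(classified$r))
  empty <- data.frame(gene = character(0), ortholog_gene = character(0),
                      substituted_by = character(0),
                      corr_paralog = numeric(0), corr_ortholog = numeric(0),
                      diff = numeric(0), age_level = character(0),
                      best = logical(0), ortholog_absent = logical(0),
                      stringsAsFactors = FALSE)
  # view pairs from both sides so genes of either species are assessed
  long <- rbind(
    data.frame(gene = classified$gene_a, partner = classified$gene_b,
               r = classified$r, relation = classified$relation,
               age_level = classified$age_level, stringsAsFactors = FALSE),
    data.frame(gene = classified$gene_b, partner = classified$gene_a,
               r = classified$r, relation = classified$relation,
               age_level = classified$age_level, stringsAsFactors = FALSE))
  long <- long[long$relation != "unannotated", , drop = FALSE]
  if (!nrow(long)) { class(empty) <- c("substitution_events", "data.frame"); return(empty) }
  out <- list()
  for (g in unique(long$gene[long$relation == "paralog"])) {
    rows <- long[long$gene == g, , drop = FALSE]
    orth <- rows[rows$relation == "ortholog", , drop = FALSE]
    par <- rows[rows$relation == "paralog", , drop = FALSE]
    orth_best <- if (nrow(orth)) max(orth$r) else 0
    orth_gene <- if (nrow(orth)) orth$partner[which.max(orth$r)] else NA_character_
    hit <- par$r - orth_best > diff_threshold
    if (!any(hit)) next
    par <- par[hit, , drop = FALSE]
    best_idx <- order(-par$r, par$partner)[1]
    out[[length(out) + 1L]] <- data.frame(
      gene = g, ortholog_gene = orth_gene, substituted_by = par$partner,
      corr_paralog = par$r, corr_ortholog = orth_best,
      diff = par$r - orth_best, age_level = par$age_level,
      best = seq_len(nrow(par)) == best_idx,
      ortholog_absent = nrow(orth) == 0,
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else empty
  res <- res[order(res$gene, -res$corr_paralog), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("substitution_events", "data.frame")
  res
}

#' Assign substitution events to cell types via enriched gene pairs
#'
#' A substitution event is attached to the cell-type pairs in whose
#' mapping the paralogous gene pair is enriched (passes the
#' differential-expression, gene-weight and expressed-fraction filters).
#' Events whose pair is enriched in no mapping remain unassigned; they
#' never enter cell-type-level statistics.
#'
#' @param events `substitution_events` from [detect_substitutions()].
#' @param enriched Data.frame with columns `type_a`, `type_b`, `gene_1`
#'   (species 1), `gene_2` (species 2), one row per enriched pair per
#'   mapping (e.g. the `passed` rows of [enriched_gene_pairs()] pooled
#'   over mappings).
#' @return Data.frame with one row per (event, cell-type pair)
#'   assignment: `gene`, `substituted_by`, `type_a`, `type_b`.
#' @export
assign_events_to_celltypes <- function(events, enriched) {
  ukey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  if (!nrow(events) || !nrow(enriched))
    return(data.frame(gene = character(0), substituted_by = character(0),
                      type_a = character(0), type_b = character(0),
                      stringsAsFactors = FALSE))
  ek <- ukey(events$gene, events$substituted_by)
  nk <- ukey(enriched$gene_1, enriched$gene_2)
  hit <- match(nk, ek)
  ok <- !is.na(hit)
  data.frame(gene = events$gene[hit[ok]],
             substituted_by = events$substituted_by[hit[ok]],
             type_a = enriched$type_a[ok], type_b = enriched$type_b[ok],
             stringsAsFactors = FALSE)
}

#' End-to-end paralog substitution analysis of a finished mapping
#'
#' Computes gene-pair correlations over the final combined manifold,
#' classifies homologous pairs by orthology-group age, detects paralog
#' substitutions, finds the enriched gene pairs of every mapped
#' cell-type pair, and assigns events to cell types.
#'
#' @param result A `samap_result`.
#' @param orthology_table Data.frame (gene_id, level, group_id).
#' @param mrca_level,level_order See [classify_pairs()].
#' @param diff_threshold Substitution correlation margin (default 0.3).
#' @param z Minimum cell-type alignment score for a mapping (default
#'   0.1).
#' @param ... Further filter arguments passed to [enriched_gene_pairs()].
#' @return List with `correlations`, `classified`, `events`, `enriched`
#'   (pooled passed pairs with their mappings), `assignments` and the
#'   `mappings` table.
#' @export
paralog_substitution_analysis <- function(result, orthology_table,
                                          mrca_level = level_order[1],
                                          level_order = DEFAULT_LEVELS,
                                          diff_threshold = 0.3, z = 0.1,
                                          ...) {
  stopifnot(inherits(result, "samap_result"))
  cors <- map_gene_correlations(result)
  classified <- classify_pairs(cors, orthology_table,
                               mrca_level = mrca_level,
                               level_order = level_order)
  events <- detect_substitutions(classified,
                                 diff_threshold = diff_threshold)
  cg <- result$combined
  labels_1 <- result$labels[[1]]; labels_2 <- result$labels[[2]]
  mappings <- celltype_alignment_scores(cg$C_1, cg$C_2, labels_1, labels_2,
                                        k = cg$k, z = z)
  m1 <- result$manifolds[[1]]; m2 <- result$manifolds[[2]]
  zt1 <- standardize_and_mask(m1, result$homology)
  zt2 <- standardize_and_mask(m2, result$homology)
  enr <- vector("list", nrow(mappings))
  for (i in seq_len(nrow(mappings))) {
    tab <- enriched_gene_pairs(
      mappings$type_a[i], mappings$type_b[i], cg$C_1, cg$C_2, zt1, zt2,
      labels_1, labels_2, result$homology,
      m1$gene_weights, m2$gene_weights, m1$lognorm, m2$lognorm, ...)
    tab <- tab[tab$passed, , drop = FALSE]
    if (nrow(tab)) {
      tab$type_a <- mappings$type_a[i]
      tab$type_b <- mappings$type_b[i]
    }
    enr[[i]] <- tab
  }
  enr <- do.call(rbind, enr[vapply(enr, nrow, integer(1)) > 0])
  if (is.null(enr))
    enr <- data.frame(gene_1 = character(0), gene_2 = character(0),
                      type_a = character(0), type_b = character(0))
  assignments <- assign_events_to_celltypes(events, enr)
  list(correlations = cors, classified = classified, events = events,
       enriched = enr, assignments = assignments, mappings = mappings)
}

#' Per-cell-type paralog substitution scores
#'
#' Each substitution event assigned to a cell type contributes
#' `1 - n_i`, where `n_i` is the gene's paralog count normalized by the
#' maximum paralog count over all genes (discounting promiscuous genes);
#' the sum is divided by the cell type's number of differentially
#' expressed genes `m_k` (discounting large expression programs).
#'
#' @param event_types Data.frame with columns `cell_type` and `gene`
#'   (one row per event-to-cell-type assignment, e.g. from enriched gene
#'   pairs).
#' @param de_gene_counts Named integer vector: differentially expressed
#'   genes per cell type (`m_k`).
#' @param paralog_counts Named integer vector: paralogs per gene.
#' @return Data.frame with `cell_type` and `score`; cell types with
#'   `m_k = 0` get `NA`.
#' @export
substitution_scores <- function(event_types, de_gene_counts,
                                paralog_counts) {
  mx <- max(paralog_counts)
  if (mx <= 0) stop("paralog_counts must contain positive counts")
  types <- names(de_gene_counts)
  score <- vapply(types, function(k) {
    mk <- de_gene_counts[[k]]
    genes <- unique(event_types$gene[event_types$cell_type == k])
    if (mk == 0) return(NA_real_)
    if (!length(genes)) return(0)
    ni <- paralog_counts[genes] / mx
    ni[is.na(ni)] <- 0
    sum(1 - ni) / mk
  }, numeric(1))
  data.frame(cell_type = types, score = unname(score),
             stringsAsFactors = FALSE)
}

#' Paralog substitution rate per evolutionary age level
#'
#' Normalizes the number of substituting paralog pairs at each
#' taxonomic level by the total number of paralog pairs at that level.
#'
#' @param events `substitution_events` (with `age_level`).
#' @param classified `homolog_classification` providing the totals.
#' @return Data.frame with `age_level`, `n_substituting`, `n_paralogs`,
#'   `rate`; levels with no paralogs are omitted (rate undefined).
#' @export
substitution_rate_by_age <- function(events, classified) {
  par <- classified[classified$relation == "paralog", , drop = FALSE]
  if (!nrow(par)) return(data.frame(age_level = character(0),
                                    n_substituting = integer(0),
                                    n_paralogs = integer(0),
                                    rate = numeric(0)))
  totals <- table(par$age_level)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  sub_keys <- unique(key(events$gene, events$substituted_by))
  par_keys <- key(par$gene_a, par$gene_b)
  sub_by_level <- table(par$age_level[par_keys %in% sub_keys])
  lv <- names(totals)
  data.frame(
    age_level = lv,
    n_substituting = as.integer(ifelse(lv %in% names(sub_by_level),
                                       sub_by_level[lv], 0)),
    n_paralogs = as.integer(totals),
    rate = as.numeric(ifelse(lv %in% names(sub_by_level),
                             sub_by_level[lv], 0)) / as.integer(totals),
    stringsAsFactors = FALSE)
}
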