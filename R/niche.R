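#' Rule for calling niche-specific gene families
#'
#' A family is niche-specific when it is present in at least
#' `min_presence_fraction` of the focal group's genomes (ceiling rule:
#' at least `ceiling(fraction * group size)` genomes) and present in at
#' most `max_background_presence` genomes of the contrasting group.
#' The defaults encode the "present in at least one-third of the focal
#' strains and missing from all contrasting strains" rule.
#'
#' @param min_presence_fraction minimum presence fraction in the focal
#'   group, in (0, 1]
#' @param max_background_presence maximum number of background genomes
#'   allowed to carry the family (0 = strict absence)
#' @return a `niche_rule` list
#' @export
niche_rule <- function(min_presence_fraction = 1 / 3,
                       max_background_presence = 0) {
  if (min_presence_fraction <= 0 || min_presence_fraction > 1)
    stop("`min_presence_fraction` must be in (0, 1]")
  if (max_background_presence < 0)
    stop("`max_background_presence` must be >= 0")
  structure(list(min_presence_fraction = min_presence_fraction,
                 max_background_presence = max_background_presence),
            class = "niche_rule")
}

#' Dispensable families shared by a genome group
#'
#' Families classified dispensable in the whole-set partition *and*
#' present in every genome of `group`.  Note that presence in genomes
#' outside the group is not restricted here; use [niche_specific()] for
#' the absence-constrained rule.
#'
#' @param matrix a [pa_matrix()]
#' @param part the [partition()] of the same matrix
#' @param group genome ids (non-empty subset of the matrix's genomes)
#' @return character vector of family ids
#' @export
shared_dispensable <- function(matrix, part, group) {
  stopifnot(inherits(matrix, "pa_matrix"), inherits(part, "pan_partition"))
  if (!length(group)) stop("`group` is empty")
  bad <- setdiff(group, genome_ids(matrix))
  if (length(bad))
    stop("unknown genomes in `group`: ", paste(bad, collapse = ", "))
  pres <- matrix$counts[, group, drop = FALSE] > 0L
  fam <- names(part$classes)[part$classes == "dispensable"]
  fam[rowSums(pres[fam, , drop = FALSE]) == length(group)]
}

#' Niche-specific gene families
#'
#' Applies a [niche_rule()] to a focal/background genome contrast:
#' presence in at least `ceiling(fraction * |focal|)` focal genomes and
#' at most `max_background_presence` background genomes.
#'
#' @param matrix a [pa_matrix()]
#' @param focal,background disjoint genome id sets
#' @param rule a [niche_rule()]
#' @return character vector of family ids
#' @export
niche_specific <- function(matrix, focal, background,
                           rule = niche_rule()) {
  stopifnot(inherits(matrix, "pa_matrix"), inherits(rule, "niche_rule"))
  if (!length(focal)) stop("`focal` is empty")
  if (length(intersect(focal, background)))
    stop("`focal` and `background` overlap")
  bad <- setdiff(c(focal, background), genome_ids(matrix))
  if (length(bad))
    stop("unknown genomes: ", paste(bad, collapse = ", "))
  pres <- matrix$counts > 0L
  need <- ceiling(rule$min_presence_fraction * length(focal))
  in_focal <- rowSums(pres[, focal, drop = FALSE])
  in_bg <- if (length(background))
    rowSums(pres[, background, drop = FALSE]) else 0L
  rownames(pres)[in_focal >= need &
                   in_bg <= rule$max_background_presence]
}

#' COG category enrichment between two family sets
#'
#' For every category, a 2x2 table (in-category / not-in-category by
#' set A / set B) is tested with a two-sided Fisher exact test; the
#' two-sided p sums all hypergeometric outcomes whose probability does
#' not exceed that of the observed table.  Families missing from
#' `cog_table` count as `"unknown"`.
#'
#' @param set_a,set_b family id vectors (need not be disjoint; at least
#'   one non-empty)
#' @param cog_table `data.frame(family, category)`
#' @param alpha significance level applied after correction
#' @param correction `"none"` (raw p, the default) or `"BH"`
#'   (Benjamini-Hochberg)
#' @return `data.frame(category, a_in, a_out, b_in, b_out, a_pct,
#'   b_pct, odds_ratio, p, p_adj, significant)`, sorted by p
#' @export
cog_enrichment <- function(set_a, set_b, cog_table, alpha = 0.05,
                           correction = c("none", "BH")) {
  correction <- match.arg(correction)
  if (!length(set_a) && !length(set_b))
    stop("both family sets are empty")
  cat_of <- stats::setNames(cog_table$category, cog_table$family)
  cat_a <- ifelse(set_a %in% names(cat_of), cat_of[set_a], "unknown")
  cat_b <- ifelse(set_b %in% names(cat_of), cat_of[set_b], "unknown")
  cats <- sort(unique(c(cat_a, cat_b)))
  rows <- lapply(cats, function(cc) {
    a_in <- sum(cat_a == cc); b_in <- sum(cat_b == cc)
    a_out <- length(cat_a) - a_in; b_out <- length(cat_b) - b_in
    tab <- matrix(c(a_in, a_out, b_in, b_out), 2)
    ft <- stats::fisher.test(tab, alternative = "two.sided")
    data.frame(category = cc, a_in = a_in, a_out = a_out,
               b_in = b_in, b_out = b_out,
               a_pct = 100 * a_in / max(1, length(cat_a)),
               b_pct = 100 * b_in / max(1, length(cat_b)),
               odds_ratio = unname(ft$estimate), p = ft$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- if (correction == "BH") stats::p.adjust(out$p, "BH")
  else out$p
  out$significant <- out$p_adj < alpha
  out[order(out$p), , drop = FALSE]
}

#' Per-species niche contrast report
#'
#' For every species (from the matrix metadata), the marine-specific
#' and land-specific family sets under `rule`, their COG category
#' distributions, and the COG enrichment of marine-specific versus
#' land-specific families.  Species with fewer than two genomes in
#' either niche are reported as `"insufficient contrast"` rather than
#' tested.
#'
#' @param matrix a [pa_matrix()] whose metadata has `niche` and
#'   `species` columns
#' @param part the [partition()] of the matrix
#' @param cog_table `data.frame(family, category)`
#' @param rule a [niche_rule()]
#' @param alpha significance level for the enrichment tests
#' @return a `niche_report`: per-species list with `status`
#'   (`"ok"`/`"insufficient contrast"`), `marine_specific`,
#'   `land_specific`, `cog_marine`, `cog_land` (category count tables)
#'   and `enrichment`; plus a `summary` data frame of counts
#' @export
niche_report <- function(matrix, part, cog_table, rule = niche_rule(),
                         alpha = 0.05) {
  stopifnot(inherits(matrix, "pa_matrix"))
  meta <- matrix$metadata
  if (is.null(meta) || !all(c("niche", "species") %in% names(meta)))
    stop("matrix metadata must provide `niche` and `species`")
  cat_of <- stats::setNames(cog_table$category, cog_table$family)
  per_species <- list()
  for (sp in sort(unique(meta$species))) {
    g <- meta$genome[meta$species == sp]
    marine <- meta$genome[meta$species == sp & meta$niche == "marine"]
    land <- meta$genome[meta$species == sp & meta$niche == "land"]
    if (length(marine) < 2 || length(land) < 2) {
      per_species[[sp]] <- list(status = "insufficient contrast",
                                n_marine = length(marine),
                                n_land = length(land))
      next
    }
    ms <- niche_specific(matrix, marine, land, rule)
    ls <- niche_specific(matrix, land, marine, rule)
    cogdist <- function(fams) {
      cc <- ifelse(fams %in% names(cat_of), cat_of[fams], "unknown")
      table(cc)
    }
    enr <- if (length(ms) || length(ls))
      cog_enrichment(ms, ls, cog_table, alpha = alpha) else NULL
    per_species[[sp]] <- list(status = "ok",
                              n_marine = length(marine),
                              n_land = length(land),
                              marine_specific = ms, land_specific = ls,
                              cog_marine = cogdist(ms),
                              cog_land = cogdist(ls),
                              enrichment = enr)
  }
  summary <- do.call(rbind, lapply(names(per_species), function(sp) {
    x <- per_species[[sp]]
    data.frame(species = sp, status = x$status,
               n_marine = x$n_marine, n_land = x$n_land,
               marine_specific = if (x$status == "ok")
                 length(x$marine_specific) else NA_integer_,
               land_specific = if (x$status == "ok")
                 length(x$land_specific) else NA_integer_)
  }))
  structure(list(species = per_species, summary = summary,
                 rule = rule, alpha = alpha),
            class = "niche_report")
}

#' @export
print.niche_report <- function(x, ...) {
  cat("niche_report (presence fraction >= ",
      format(x$rule$min_presence_fraction, digits = 3),
      ", background <= ", x$rule$max_background_presence, ")\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
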