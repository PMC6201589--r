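#' One-tailed Fisher enrichment of physiological traits among markers
#'
#' For every (site, association type, trait sub-category) combination, tests
#' whether the sub-category is enriched among the focal marker OTUs (that
#' site and type) relative to the background of markers with the same
#' association type at other sites. Trait information is recorded at the
#' genus level and extrapolated to member OTUs through `genus_map`; OTUs with
#' no recorded value for a category are excluded from that category's table,
#' and multi-valued traits count an OTU once per alternative. The one-tailed
#' (greater) hypergeometric p-values are Benjamini-Hochberg adjusted jointly
#' across all produced records; a record is flagged enriched when its
#' adjusted p is at or below `alpha`. Indeterminate-sign markers take part in
#' neither focal nor background sets.
#'
#' @param bset a [BiomarkerSet].
#' @param traits data.frame with columns `genus`, `category`, `value` (one
#'   row per recorded value; a genus may carry several values per category).
#' @param genus_map data.frame with columns `otu_id`, `genus`.
#' @param alpha significance level after adjustment (default 0.05).
#' @return data.frame with one row per tested record: `site`, `type`,
#'   `category`, `value`, the 2x2 counts `a`, `b`, `c`, `d`, `p`, `p_adj`,
#'   `enriched`. Records with an empty focal or background margin are
#'   skipped; the reasons are kept in the `"skipped"` attribute.
#' @export
enrichTraits <- function(bset, traits, genus_map, alpha = 0.05) {
  m <- markers(bset)
  m <- m[!is.na(m$sign), , drop = FALSE]
  skipped <- character(0)
  rows <- list()
  if (nrow(m) && nrow(traits)) {
    m$genus <- genus_map$genus[match(m$otu_id, genus_map$otu_id)]
    cats <- unique(traits$category)
    for (s in sort(unique(m$site))) for (ty in c(1L, -1L)) {
      focal <- m[m$site == s & m$sign == ty, , drop = FALSE]
      backg <- m[m$site != s & m$sign == ty, , drop = FALSE]
      # an OTU negatively associated with several sites would otherwise sit
      # on both margins; background keeps only OTUs outside the focal set
      backg <- backg[!backg$otu_id %in% focal$otu_id, , drop = FALSE]
      for (cat in cats) {
        tr_cat <- traits[traits$category == cat, , drop = FALSE]
        focal_known <- focal[focal$genus %in% tr_cat$genus, , drop = FALSE]
        backg_known <- backg[backg$genus %in% tr_cat$genus, , drop = FALSE]
        if (!nrow(focal_known) || !nrow(backg_known)) {
          skipped <- c(skipped, sprintf(
            "%s/%s/%s: empty %s set", s, ifelse(ty > 0, "+", "-"), cat,
            if (!nrow(focal_known)) "focal" else "background"))
          next
        }
        has <- function(df, val) vapply(df$genus, function(g)
          val %in% tr_cat$value[tr_cat$genus == g], logical(1))
        for (val in unique(tr_cat$value)) {
          a <- sum(has(focal_known, val))
          b <- nrow(focal_known) - a
          cc <- sum(has(backg_known, val))
          d <- nrow(backg_known) - cc
          p <- fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE),
                           alternative = "greater")$p.value
          rows[[length(rows) + 1]] <- data.frame(
            site = s, type = ifelse(ty > 0, "+", "-"), category = cat,
            value = val, a = a, b = b, c = cc, d = d, p = p,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
  else data.frame(site = character(0), type = character(0),
                  category = character(0), value = character(0),
                  a = integer(0), b = integer(0), c = integer(0),
                  d = integer(0), p = numeric(0))
  out$p_adj <- p.adjust(out$p, method = "BH")
  out$enriched <- out$p_adj <= alpha
  attr(out, "skipped") <- skipped
  out
}
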