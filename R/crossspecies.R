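# Cross-species regulon comparison through orthologue maps: congruence
# classes of differential expression, common peak positions, and the
# three-species intersection.

#' Filter an orthologue map to one-to-one pairs
#'
#' Any identifier appearing more than once on its side removes all its
#' rows (many-to-many orthology is dropped, with a message giving the
#' count): per-gene congruence calls need unambiguous pairs.
#'
#' @param map data.frame with columns `id_a`, `id_b`.
#' @return filtered map.
#' @export
filter_ortholog_map <- function(map) {
  dup_a <- map$id_a %in% map$id_a[duplicated(map$id_a)]
  dup_b <- map$id_b %in% map$id_b[duplicated(map$id_b)]
  drop <- dup_a | dup_b
  if (any(drop)) {
    message("dropped ", sum(drop),
            " non-one-to-one orthologue row(s)")
  }
  out <- map[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

deg_sign <- function(deg, ids, alpha, use_adjusted) {
  idx <- match(ids, deg$gene_id)
  p <- if (use_adjusted) deg$padj[idx] else deg$pvalue[idx]
  lfc <- deg$log2fc[idx]
  out <- rep("ns", length(ids))
  sig <- !is.na(p) & p <= alpha & !is.na(lfc) & lfc != 0
  out[sig & lfc > 0] <- "+"
  out[sig & lfc < 0] <- "-"
  out
}

#' Congruence of two species' differential-expression calls
#'
#' For every one-to-one orthologous pair with at least one significant
#' side, records the two regulation signs and the congruence class:
#' `convergent_activated` (+,+), `convergent_repressed` (-,-),
#' `divergent` (opposite signs), `unique_a`/`unique_b` (significant on
#' one side only). A gene absent from a species' table counts as
#' not-significant there. The summary satisfies
#' `common = convergent_activated + convergent_repressed + divergent`.
#'
#' @param deg_a,deg_b DEG tables (columns `gene_id`, `log2fc`, `pvalue`,
#'   `padj`).
#' @param map orthologue map (`id_a`, `id_b`); filtered to 1:1
#'   internally.
#' @param alpha significance threshold per species.
#' @param use_adjusted use `padj` instead of `pvalue`.
#' @return list with `records` (data.frame `id_a`, `id_b`, `sign_a`,
#'   `sign_b`, `klass`) and `summary` (named numeric vector).
#' @export
compare_regulons <- function(deg_a, deg_b, map, alpha = 0.05,
                             use_adjusted = FALSE) {
  map <- filter_ortholog_map(map)
  if (anyDuplicated(map$id_a) || anyDuplicated(map$id_b)) {
    stop("duplicate ids remain after one-to-one filtering", call. = FALSE)
  }
  sa <- deg_sign(deg_a, map$id_a, alpha, use_adjusted)
  sb <- deg_sign(deg_b, map$id_b, alpha, use_adjusted)
  keep <- sa != "ns" | sb != "ns"
  rec <- data.frame(id_a = map$id_a[keep], id_b = map$id_b[keep],
                    sign_a = sa[keep], sign_b = sb[keep],
                    stringsAsFactors = FALSE)
  rec$klass <- ifelse(rec$sign_a == "+" & rec$sign_b == "+",
                      "convergent_activated",
               ifelse(rec$sign_a == "-" & rec$sign_b == "-",
                      "convergent_repressed",
               ifelse(rec$sign_a != "ns" & rec$sign_b != "ns",
                      "divergent",
               ifelse(rec$sign_a != "ns", "unique_a", "unique_b"))))
  cnt <- function(k) sum(rec$klass == k)
  summary <- c(
    convergent_activated = cnt("convergent_activated"),
    convergent_repressed = cnt("convergent_repressed"),
    divergent = cnt("divergent"),
    unique_a = cnt("unique_a"),
    unique_b = cnt("unique_b"),
    common = cnt("convergent_activated") + cnt("convergent_repressed") +
      cnt("divergent"),
    n_records = nrow(rec)
  )
  list(records = rec, summary = summary)
}

gene_orientation_classes <- function(assignments, ids) {
  fl <- assignments$location_flags[match(ids, assignments$gene_id)]
  fl[is.na(fl)] <- ""
  lapply(fl, function(x) {
    cls <- character(0)
    if (grepl("b", x, fixed = TRUE)) cls <- c(cls, "upstream_of")
    if (grepl("a", x, fixed = TRUE)) cls <- c(cls, "inside")
    cls
  })
}

#' Peaks in common positions relative to orthologous genes
#'
#' A pair of orthologous genes shares a common peak when both species
#' carry a peak assigned to their member with the same orientation class
#' (upstream promoter site vs site inside the coding region). With
#' `strict = FALSE`, pairs where both sides have peak evidence but in
#' different orientation classes are also reported, flagged
#' `orientation_match = FALSE`.
#'
#' @param assignments_a,assignments_b assignment tables from
#'   [integrate_regulon()].
#' @param map orthologue map; filtered to 1:1 internally.
#' @param strict require the same orientation class.
#' @return data.frame `id_a`, `id_b`, `peaks_a`, `peaks_b`, `class_a`,
#'   `class_b`, `orientation_match`.
#' @export
common_peaks <- function(assignments_a, assignments_b, map,
                         strict = TRUE) {
  map <- filter_ortholog_map(map)
  empty <- data.frame(id_a = character(0), id_b = character(0),
                      peaks_a = character(0), peaks_b = character(0),
                      class_a = character(0), class_b = character(0),
                      orientation_match = logical(0),
                      stringsAsFactors = FALSE)
  if (nrow(map) == 0L) return(empty)
  ev <- function(assign, ids) {
    x <- assign$evidence_peaks[match(ids, assign$gene_id)]
    x[is.na(x)] <- ""
    x
  }
  pa <- ev(assignments_a, map$id_a)
  pb <- ev(assignments_b, map$id_b)
  ca <- gene_orientation_classes(assignments_a, map$id_a)
  cb <- gene_orientation_classes(assignments_b, map$id_b)
  keep <- nzchar(pa) & nzchar(pb)
  if (!any(keep)) return(empty)
  idx <- which(keep)
  match_cls <- vapply(idx, function(i) {
    length(intersect(ca[[i]], cb[[i]])) > 0L
  }, logical(1L))
  out <- data.frame(
    id_a = map$id_a[idx], id_b = map$id_b[idx],
    peaks_a = pa[idx], peaks_b = pb[idx],
    class_a = vapply(ca[idx], paste, "", collapse = ","),
    class_b = vapply(cb[idx], paste, "", collapse = ","),
    orientation_match = match_cls,
    stringsAsFactors = FALSE
  )
  if (strict) out <- out[out$orientation_match, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Three-species intersection of direct regulation
#'
#' Composes an A-B and an A-C orthologue map and reports the triples that
#' are classified `direct` with the same regulation sign in all three
#' assignment tables. Identifiers mapping to more than one partner after
#' one-to-one filtering are dropped with a warning that gives the count.
#'
#' @param assignments_a,assignments_b,assignments_c assignment tables
#'   from [integrate_regulon()].
#' @param map_ab,map_ac orthologue maps anchored on species A.
#' @return data.frame `id_a`, `id_b`, `id_c`, `regulation`.
#' @export
three_way <- function(assignments_a, assignments_b, assignments_c,
                      map_ab, map_ac) {
  map_ab <- filter_ortholog_map(map_ab)
  map_ac <- filter_ortholog_map(map_ac)
  ids <- intersect(map_ab$id_a, map_ac$id_a)
  n_drop <- length(union(map_ab$id_a, map_ac$id_a)) - length(ids)
  if (n_drop > 0L) {
    warning(n_drop, " gene(s) present in only one map were dropped ",
            "from the three-way composition")
  }
  empty <- data.frame(id_a = character(0), id_b = character(0),
                      id_c = character(0), regulation = character(0),
                      stringsAsFactors = FALSE)
  if (length(ids) == 0L) return(empty)
  get <- function(assign, g, col) {
    assign[[col]][match(g, assign$gene_id)]
  }
  id_b <- map_ab$id_b[match(ids, map_ab$id_a)]
  id_c <- map_ac$id_b[match(ids, map_ac$id_a)]
  cat_a <- get(assignments_a, ids, "category")
  cat_b <- get(assignments_b, id_b, "category")
  cat_c <- get(assignments_c, id_c, "category")
  reg_a <- get(assignments_a, ids, "regulation")
  reg_b <- get(assignments_b, id_b, "regulation")
  reg_c <- get(assignments_c, id_c, "regulation")
  keep <- !is.na(cat_a) & !is.na(cat_b) & !is.na(cat_c) &
    cat_a == "direct" & cat_b == "direct" & cat_c == "direct" &
    reg_a == reg_b & reg_b == reg_c
  if (!any(keep)) return(empty)
  out <- data.frame(id_a = ids[keep], id_b = id_b[keep],
                    id_c = id_c[keep], regulation = reg_a[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
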