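network_pair_levels <- function() {
  c("DMN", "ASN", "LECN", "DMN-ASN", "ASN-LECN", "LECN-DMN")
}

# unordered network pair -> fixed category label
pair_category <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  within <- a == b
  out <- character(length(a))
  out[within] <- a[within]
  if (any(!within)) {
    canon <- c("ASN|DMN" = "DMN-ASN", "ASN|LECN" = "ASN-LECN",
               "DMN|LECN" = "LECN-DMN")
    key <- paste(pmin(a[!within], b[!within]), pmax(a[!within], b[!within]), sep = "|")
    lab <- canon[key]
    if (any(is.na(lab))) stopf("unknown network pair(s): %s", paste(unique(key[is.na(lab)]), collapse = ", "))
    out[!within] <- lab
  }
  out
}

edge_networks <- function(selected, annotation) {
  m <- nrow(annotation)
  if (any(selected$edge_id >= edge_count(m))) stopf("selected edge id out of range for %d nodes", m)
  ann <- annotation[order(annotation$node_id), ]
  ei <- edge_index(m)
  ni <- ei$node_i[selected$edge_id + 1L]
  nj <- ei$node_j[selected$edge_id + 1L]
  list(node_i = ni, node_j = nj,
       network_i = ann$network[ni + 1L], network_j = ann$network[nj + 1L],
       group_i = ann$region_group[ni + 1L], group_j = ann$region_group[nj + 1L],
       label_i = ann$label[ni + 1L], label_j = ann$label[nj + 1L])
}

#' Classify selected edges into signed network-pair categories
#'
#' Places every selected edge into one of six categories -- within-network
#' (DMN, ASN, LECN) or between-network (DMN-ASN, ASN-LECN, LECN-DMN,
#' order-insensitive) -- split by the sign of its worry coefficient.
#' Zero-coefficient edges count as positive, with a warning.
#'
#' @param selected An [hc_select()] result.
#' @param annotation The `node_annotation` for the connectome the selection
#'   came from (networks among DMN, ASN, LECN).
#' @return A data frame of class `network_pair_counts` with columns
#'   `category, positive, negative` (six rows, fixed order); the twelve
#'   cells sum to `nrow(selected)`.
#' @export
classify_edges <- function(selected, annotation) {
  if (any(is.na(annotation$network))) stopf("every node needs a network annotation")
  if (!all(levels(factor(annotation$network)) %in% c("DMN", "ASN", "LECN"))) {
    stopf("networks must be among DMN, ASN, LECN")
  }
  lv <- network_pair_levels()
  if (nrow(selected) == 0L) {
    out <- data.frame(category = factor(lv, levels = lv),
                      positive = integer(6), negative = integer(6))
  } else {
    en <- edge_networks(selected, annotation)
    category <- factor(pair_category(en$network_i, en$network_j), levels = lv)
    sgn <- selected$sign
    if (any(sgn == 0)) {
      warnf("%d selected edge(s) with beta = 0 counted as positive", sum(sgn == 0))
      sgn[sgn == 0] <- 1
    }
    out <- data.frame(
      category = factor(lv, levels = lv),
      positive = as.integer(table(category[sgn > 0])[lv]),
      negative = as.integer(table(category[sgn < 0])[lv])
    )
    out$positive[is.na(out$positive)] <- 0L
    out$negative[is.na(out$negative)] <- 0L
  }
  attr(out, "n_selected") <- nrow(selected)
  class(out) <- c("network_pair_counts", class(out))
  out
}

#' Signed weighted degree centrality of selected edges
#'
#' Each selected edge contributes its standardized worry coefficient
#' `beta_std` to both of its endpoint regions: to the positive map when
#' `beta_std > 0`, to the negative map otherwise. A region therefore
#' reaches a high intensity either through many relevant edges or through
#' strongly associated ones. Summing positive and negative strata
#' separately avoids cancellation.
#'
#' @param selected An [hc_select()] result.
#' @param annotation The matching `node_annotation`.
#' @param level `"node"` (per node) or `"region_group"` (node maps
#'   aggregated over anatomical groups).
#' @return A data frame of class `centrality_map` with columns
#'   `region, positive_sum, negative_sum` (`positive_sum >= 0`,
#'   `negative_sum <= 0`), covering every region at the requested level.
#' @export
signed_degree_centrality <- function(selected, annotation,
                                     level = c("node", "region_group")) {
  level <- match.arg(level)
  ann <- annotation[order(annotation$node_id), ]
  if (level == "node" && anyDuplicated(ann$label)) {
    stopf("node labels must be unique for node-level centrality")
  }
  regions <- if (level == "node") ann$label else levels(factor(ann$region_group))
  pos <- setNames(numeric(length(regions)), regions)
  neg <- pos
  if (nrow(selected) > 0L) {
    en <- edge_networks(selected, annotation)
    reg_i <- if (level == "node") en$label_i else as.character(en$group_i)
    reg_j <- if (level == "node") en$label_j else as.character(en$group_j)
    for (e in seq_len(nrow(selected))) {
      w <- selected$beta_std[e]
      if (w > 0) {
        pos[reg_i[e]] <- pos[reg_i[e]] + w
        pos[reg_j[e]] <- pos[reg_j[e]] + w
      } else if (w < 0) {
        neg[reg_i[e]] <- neg[reg_i[e]] + w
        neg[reg_j[e]] <- neg[reg_j[e]] + w
      }
    }
  }
  out <- data.frame(region = regions, positive_sum = unname(pos),
                    negative_sum = unname(neg), row.names = NULL)
  attr(out, "level") <- level
  class(out) <- c("centrality_map", class(out))
  out
}

#' Export plotting-ready summary tables
#'
#' Writes four artifacts to `dir`: `edges.csv` (selected edges with
#' endpoint networks and region groups), `network_pair_counts.csv` (the
#' six signed within/between-network categories), `centrality.csv`
#' (signed weighted degree centrality), and `summary.json` (max HC,
#' selection rank, counts). Rows are canonically ordered and floats
#' formatted with 6 significant digits so identical inputs re-export
#' byte-identically.
#'
#' @param selected An [hc_select()] result.
#' @param counts A [classify_edges()] result.
#' @param centrality A [signed_degree_centrality()] result.
#' @param annotation The matching `node_annotation`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
export_summary <- function(selected, counts, centrality, annotation, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(edges = file.path(dir, "edges.csv"),
             counts = file.path(dir, "network_pair_counts.csv"),
             centrality = file.path(dir, "centrality.csv"),
             summary = file.path(dir, "summary.json"))

  if (nrow(selected) > 0L) {
    en <- edge_networks(selected, annotation)
    ed <- data.frame(node_i = en$node_i, node_j = en$node_j,
                     network_i = as.character(en$network_i),
                     network_j = as.character(en$network_j),
                     region_group_i = as.character(en$group_i),
                     region_group_j = as.character(en$group_j),
                     beta_std = selected$beta_std, sign = selected$sign,
                     p = selected$p,
                     category = pair_category(en$network_i, en$network_j),
                     edge_id = selected$edge_id)
    ed <- ed[order(ed$category, ed$edge_id), ]
  } else {
    ed <- data.frame(node_i = integer(0), node_j = integer(0),
                     network_i = character(0), network_j = character(0),
                     region_group_i = character(0), region_group_j = character(0),
                     beta_std = numeric(0), sign = numeric(0), p = numeric(0),
                     category = character(0), edge_id = integer(0))
  }
  hdr <- "node_i,node_j,network_i,network_j,region_group_i,region_group_j,beta_std,sign,p"
  lines <- c(hdr, if (nrow(ed)) sprintf(
    "%d,%d,%s,%s,%s,%s,%s,%d,%s", ed$node_i, ed$node_j, ed$network_i,
    ed$network_j, ed$region_group_i, ed$region_group_j, fmt_num(ed$beta_std),
    as.integer(ed$sign), fmt_num(ed$p)))
  write_lines_atomic(lines, paths[["edges"]])

  write_lines_atomic(
    c("category,positive,negative",
      sprintf("%s,%d,%d", as.character(counts$category), counts$positive, counts$negative)),
    paths[["counts"]])

  write_lines_atomic(
    c("region,positive_sum,negative_sum",
      if (nrow(centrality)) sprintf("%s,%s,%s", centrality$region,
                                    fmt_num(centrality$positive_sum),
                                    fmt_num(centrality$negative_sum))),
    paths[["centrality"]])

  summary <- list(
    hc_max = attr(selected, "hc_max"),
    i_star = attr(selected, "i_star"),
    n_selected = nrow(selected),
    category_totals = setNames(as.list(counts$positive + counts$negative),
                               as.character(counts$category)),
    n_positive = sum(counts$positive),
    n_negative = sum(counts$negative)
  )
  jsonlite::write_json(summary, paths[["summary"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
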