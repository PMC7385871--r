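#' Select variants for graph construction
#'
#' Implements the variant prioritisation modes used when augmenting a linear
#' backbone: alternate-allele-frequency thresholding within one population
#' (strictly greater than the threshold), count-matching across populations
#' (every population's passing set subsampled to the smallest passing count),
#' pooled-frequency (pan) selection, random draws that ignore frequency and
#' phase, a personalized set holding exactly one sample's variants, and the
#' empty set. Alleles observed only in `exclude_samples` are removed before
#' any selection (the samples used for read simulation must not contribute
#' private alleles to the graphs they are evaluated on).
#'
#' @param panel a [simulate_population()] panel
#' @param mode one of `"threshold"`, `"count_matched"`, `"pan"`,
#'   `"random_pool"`, `"personalized"`, `"empty"`
#' @param pops population label(s); for `count_matched`, all populations to
#'   be matched; for `pan`, the populations pooled
#' @param threshold alternate allele frequency threshold in \[0, 1\]
#' @param n_target number of variants for `random_pool`
#' @param sample sample id for `personalized`
#' @param exclude_samples sample ids whose private alleles are dropped first
#' @param pool optional variant id vector restricting `random_pool` draws
#' @param seed integer seed for the random draws
#' @return an object of class `variant_set` (or, for `count_matched`, a named
#'   list of them, one per population): list with `ids`, `variants` (tibble
#'   rows of the panel), `mode`, `threshold`, `pop`
#' @export
select_variants <- function(panel, mode = c("threshold", "count_matched",
                                            "pan", "random_pool",
                                            "personalized", "empty"),
                            pops = NULL, threshold = 0.0, n_target = NULL,
                            sample = NULL, exclude_samples = character(0),
                            pool = NULL, seed = NULL) {
  mode <- match.arg(mode)
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  ids_all <- panel$variants$id
  keep <- rep(TRUE, length(ids_all))
  if (length(exclude_samples) > 0 && ncol(panel$haplotypes) > 0) {
    ex_rows <- .hap_rows(panel, sample = exclude_samples)
    in_rows <- setdiff(seq_len(nrow(panel$haplotypes)), ex_rows)
    priv <- colSums(panel$haplotypes[ex_rows, , drop = FALSE]) > 0 &
      colSums(panel$haplotypes[in_rows, , drop = FALSE]) == 0
    keep <- !priv
  }
  mkset <- function(ids, pop = NA_character_) {
    structure(list(ids = ids,
                   variants = panel$variants[match(ids, ids_all), , drop = FALSE],
                   mode = mode, threshold = threshold, pop = pop),
              class = "variant_set")
  }
  hap_pop <- rep(panel$samples$pop, each = 2)
  af_pop <- function(p) {
    rows <- which(hap_pop %in% p)
    colMeans(panel$haplotypes[rows, , drop = FALSE])
  }
  switch(mode,
    empty = mkset(character(0)),
    personalized = {
      if (is.null(sample)) stop("personalized mode requires `sample`")
      rows <- .hap_rows(panel, sample = sample)
      carried <- colSums(panel$haplotypes[rows, , drop = FALSE]) > 0
      mkset(ids_all[carried], pop = panel$samples$pop[
        panel$samples$sample == sample][1])
    },
    threshold = {
      if (is.null(pops) || length(pops) != 1)
        stop("threshold mode requires a single population")
      af <- af_pop(pops)
      mkset(ids_all[keep & af > threshold], pop = pops)
    },
    pan = {
      if (is.null(pops)) pops <- unique(panel$samples$pop)
      af <- af_pop(pops)
      mkset(ids_all[keep & af > threshold], pop = paste(pops, collapse = "+"))
    },
    random_pool = {
      if (is.null(n_target)) stop("random_pool mode requires `n_target`")
      cand <- if (is.null(pool)) ids_all[keep] else intersect(pool, ids_all[keep])
      if (n_target > length(cand))
        stop("n_target exceeds the size of the variant pool")
      mkset(sort(sample(cand, n_target)))
    },
    count_matched = {
      if (is.null(pops) || length(pops) < 2)
        stop("count_matched mode requires at least two populations")
      passing <- lapply(pops, function(p) ids_all[keep & af_pop(p) > threshold])
      m <- min(vapply(passing, length, 0L))
      out <- lapply(passing, function(v)
        if (length(v) > m) sort(sample(v, m)) else v)
      stats::setNames(lapply(seq_along(pops), function(i)
        mkset(out[[i]], pop = pops[i])), pops)
    })
}

#' @export
print.variant_set <- function(x, ...) {
  cat("<variant_set> ", length(x$ids), " variants (mode=", x$mode,
      if (!is.na(x$pop)) paste0(", pop=", x$pop), ")\n", sep = "")
  invisible(x)
}

#' Build a variation graph from a reference backbone and a variant set
#'
#' The backbone is split at allele boundaries and chunked into nodes of
#' nominal length `max_node_len` (the final chunk of each segment absorbs the
#' remainder). Each SNP contributes a parallel single-base node, each
#' insertion an extra node between its flanking backbone nodes, and each
#' deletion a bypass edge around the deleted backbone node(s). The result is
#' a directed acyclic bubble graph whose backbone path spells the reference
#' exactly.
#'
#' @param ref a [generate_reference()] reference
#' @param vset a [select_variants()] variant set (or `NULL` for an empty
#'   graph)
#' @param max_node_len nominal maximum node length (bp)
#' @return object of class `variation_graph`: `nodes` (tibble id, seq,
#'   ref_start, ref_end; alternate nodes have `NA` coordinates), `edges`
#'   (tibble from, to), `backbone` (integer node ids), `bubbles` (per-variant
#'   list: variant row, skipped backbone ids, alternate node id), `variants`
#'   (tibble), `ref`
#' @export
build_graph <- function(ref, vset = NULL, max_node_len = 32L) {
  L <- ref$length
  v <- if (is.null(vset) || length(vset$ids) == 0) {
    tibble::tibble(id = character(0), pos = integer(0), ref = character(0),
                   alt = character(0), vclass = character(0),
                   length_delta = integer(0))
  } else vset$variants[order(vset$variants$pos), , drop = FALSE]
  rlen <- nchar(v$ref)
  if (nrow(v) > 0) {
    if (any(v$pos < 0) || any(v$pos + rlen > L)) stop("variant out of range")
    if (any(v$pos[-1] < (v$pos + rlen)[-nrow(v)])) stop("overlapping variants")
  }
  # allele boundaries on the backbone (0-based cut positions)
  is_snp <- v$vclass == "SNP"; is_ins <- v$vclass == "INS"
  is_del <- v$vclass == "DEL"
  cuts <- c(v$pos[is_snp], v$pos[is_snp] + 1L,
            v$pos[is_ins] + 1L,
            v$pos[is_del] + 1L, (v$pos + rlen)[is_del])
  cuts <- sort(unique(c(0L, cuts[cuts > 0 & cuts < L], L)))
  # chunk each inter-cut segment: floor(len/max) chunks, last absorbs remainder
  seglen <- diff(cuts)
  nchunk <- pmax(1L, seglen %/% max_node_len)
  starts <- rep(cuts[-length(cuts)], nchunk) +
    max_node_len * (sequence(nchunk) - 1L)
  ends <- c(starts[-1], L)
  nb <- length(starts)
  nodes <- tibble::tibble(id = seq_len(nb),
                          seq = substring(ref$sequence, starts + 1L, ends),
                          ref_start = starts, ref_end = ends)
  e_from <- if (nb > 1) seq_len(nb - 1) else integer(0)
  e_to <- if (nb > 1) 2:nb else integer(0)
  backbone <- seq_len(nb)
  node_at <- function(p) match(p, starts)          # backbone node starting at p
  node_end_at <- function(p) match(p, ends)        # backbone node ending at p
  n_alt <- sum(is_snp) + sum(is_ins)
  alt_id <- integer(nrow(v)); alt_id[is_snp | is_ins] <- nb + seq_len(n_alt)
  alt_seq <- character(0); alt_ids <- integer(0)
  bubbles <- stats::setNames(vector("list", nrow(v)), v$id)
  if (any(is_snp)) {
    rn <- node_at(v$pos[is_snp])
    nxt <- node_at(v$pos[is_snp] + 1L)
    ai <- alt_id[is_snp]
    ok_prev <- rn > 1
    e_from <- c(e_from, rn[ok_prev] - 1L, ai[!is.na(nxt)])
    e_to <- c(e_to, ai[ok_prev], nxt[!is.na(nxt)])
    alt_seq <- c(alt_seq, v$alt[is_snp]); alt_ids <- c(alt_ids, ai)
    for (k in which(is_snp))
      bubbles[[v$id[k]]] <- list(variant = v[k, ], skip = node_at(v$pos[k]),
                                 alt = alt_id[k])
  }
  if (any(is_ins)) {
    left <- node_end_at(v$pos[is_ins] + 1L)
    rightp <- node_at(v$pos[is_ins] + 1L)
    ai <- alt_id[is_ins]
    e_from <- c(e_from, left, ai[!is.na(rightp)])
    e_to <- c(e_to, ai, rightp[!is.na(rightp)])
    alt_seq <- c(alt_seq, substr(v$alt[is_ins], 2L, nchar(v$alt[is_ins])))
    alt_ids <- c(alt_ids, ai)
    for (k in which(is_ins))
      bubbles[[v$id[k]]] <- list(variant = v[k, ], skip = integer(0),
                                 alt = alt_id[k])
  }
  if (any(is_del)) {
    a <- v$pos[is_del] + 1L; b <- (v$pos + rlen)[is_del]
    first <- node_at(a); lastn <- node_end_at(b)
    nxt <- node_at(b)
    e_from <- c(e_from, (first - 1L)[!is.na(nxt)])
    e_to <- c(e_to, nxt[!is.na(nxt)])
    dk <- which(is_del)
    for (j in seq_along(dk))
      bubbles[[v$id[dk[j]]]] <- list(variant = v[dk[j], ],
                                     skip = first[j]:lastn[j],
                                     alt = NA_integer_)
  }
  if (n_alt > 0) {
    ord <- order(alt_ids)
    nodes <- rbind(nodes,
                   tibble::tibble(id = alt_ids[ord], seq = alt_seq[ord],
                                  ref_start = NA_integer_,
                                  ref_end = NA_integer_))
  }
  edges <- unique(tibble::tibble(from = e_from, to = e_to))
  # compact per-variant table used for fast haplotype walks
  bubble_tbl <- tibble::tibble(
    id = v$id, vclass = v$vclass,
    alt = ifelse(is_snp | is_ins, alt_id, NA_integer_),
    snp_skip = ifelse(is_snp, vapply(bubbles, function(b)
      if (length(b$skip) == 1) b$skip else NA_integer_, 0L)[v$id],
      NA_integer_),
    ins_anchor = ifelse(is_ins, node_end_at(v$pos + 1L), NA_integer_))
  structure(list(nodes = nodes, edges = edges, backbone = backbone,
                 bubbles = bubbles, bubble_tbl = bubble_tbl, variants = v,
                 ref = ref, max_node_len = as.integer(max_node_len)),
            class = "variation_graph")
}

#' @export
print.variation_graph <- function(x, ...) {
  cat("<variation_graph> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges, ", length(x$bubbles), " variant bubble(s)\n", sep = "")
  invisible(x)
}

#' Spell the sequence of a node walk
#' @param graph a [build_graph()] graph
#' @param walk integer node ids
#' @export
walk_sequence <- function(graph, walk) {
  paste(graph$nodes$seq[match(walk, graph$nodes$id)], collapse = "")
}

# walk for one haplotype: backbone with bubbles applied where carried.
# Variants absent from the graph degrade to the reference path.
.hap_walk <- function(graph, carried_ids) {
  bt <- graph$bubble_tbl[graph$bubble_tbl$id %in% carried_ids, , drop = FALSE]
  walk <- graph$backbone
  snp <- bt[bt$vclass == "SNP", , drop = FALSE]
  if (nrow(snp) > 0) walk[match(snp$snp_skip, walk)] <- snp$alt
  del_ids <- bt$id[bt$vclass == "DEL"]
  if (length(del_ids) > 0) {
    drop <- unlist(lapply(graph$bubbles[del_ids], `[[`, "skip"))
    walk <- walk[!walk %in% drop]
  }
  ins <- bt[bt$vclass == "INS", , drop = FALSE]
  if (nrow(ins) > 0) {
    at <- match(ins$ins_anchor, walk)
    key <- c(2 * seq_along(walk), 2 * at + 1L)
    walk <- c(walk, ins$alt)[order(key)]
  }
  walk
}

#' Embed haplotype walks into a graph
#'
#' One source-to-sink walk per haplotype of the requested samples. Variants
#' carried by a haplotype but absent from the graph degrade to the reference
#' path; spelling a walk reproduces the haplotype sequence restricted to
#' graph-represented variants.
#'
#' @param graph a [build_graph()] graph
#' @param panel the panel the haplotypes come from
#' @param samples sample ids to embed
#' @return object of class `haplotype_index`: named list of integer node-id
#'   walks, names `<sample>_h1` / `<sample>_h2`
#' @export
embed_haplotypes <- function(graph, panel, samples) {
  walks <- list()
  for (s in samples) {
    rows <- .hap_rows(panel, sample = s)
    for (h in 1:2) {
      carried <- colnames(panel$haplotypes)[
        panel$haplotypes[rows[h], ] == 1L]
      walks[[paste0(s, "_h", h)]] <- .hap_walk(graph, carried)
    }
  }
  structure(walks, class = "haplotype_index")
}

# successors list of a graph (by node id)
.graph_succ <- function(graph) {
  succ <- vector("list", nrow(graph$nodes))
  for (i in seq_len(nrow(graph$edges)))
    succ[[graph$edges$from[i]]] <- c(succ[[graph$edges$from[i]]],
                                     graph$edges$to[i])
  succ
}

#' Graph topology statistics
#'
#' Node and edge counts, the edge-to-node ratio, total sequence length, and
#' the number of distinct k-length sequence paths (k-mer paths). Without a
#' haplotype index all paths through the bubbles are counted (capped at
#' `cap`); with one, only k-mers lying on embedded haplotype walks count,
#' de-duplicated by the node path they traverse.
#'
#' @param graph a [build_graph()] graph
#' @param hapindex a [embed_haplotypes()] index or `NULL`
#' @param k k-mer length (>= 1)
#' @param cap stop counting k-mer paths at this many (sets `capped`)
#' @return list with `n_nodes`, `n_edges`, `edge_node_ratio`, `total_length`,
#'   `kmer_paths`, `capped`
#' @export
graph_stats <- function(graph, hapindex = NULL, k = 21L, cap = 1e7) {
  stopifnot(k >= 1)
  n_nodes <- nrow(graph$nodes)
  n_edges <- nrow(graph$edges)
  lens <- nchar(graph$nodes$seq)
  total <- sum(lens)
  kcount <- 0
  capped <- FALSE
  if (is.null(hapindex)) {
    succ <- .graph_succ(graph)
    memo <- new.env(parent = emptyenv())
    # number of distinct node paths starting at `node` covering >= r bases
    paths_from <- function(node, r) {
      if (lens[node] >= r) return(1)
      key <- paste0(node, ":", r)
      got <- memo[[key]]
      if (!is.null(got)) return(got)
      s <- succ[[node]]
      val <- if (length(s) == 0) 0
             else sum(vapply(s, function(x) paths_from(x, r - lens[node]), 0))
      memo[[key]] <- val
      val
    }
    for (nd in graph$nodes$id) {
      for (o in seq_len(lens[nd]) - 1L) {
        rem <- k - (lens[nd] - o)
        kcount <- kcount + if (rem <= 0) 1 else {
          s <- succ[[nd]]
          if (length(s) == 0) 0
          else sum(vapply(s, function(x) paths_from(x, rem), 0))
        }
        if (kcount >= cap) { capped <- TRUE; break }
      }
      if (capped) break
    }
  } else {
    sigs <- character(0)
    for (w in hapindex) {
      wl <- lens[match(w, graph$nodes$id)]
      cum <- cumsum(wl)
      start0 <- c(0, cum[-length(cum)])
      total_w <- cum[length(cum)]
      if (total_w < k) next
      for (s0 in 0:(total_w - k)) {
        ni <- findInterval(s0, start0)      # 1-based walk index of start
        off <- s0 - start0[ni]
        nj <- findInterval(s0 + k - 1, start0)
        sigs <- c(sigs, paste(c(off, w[ni:nj]), collapse = "."))
        if (length(sigs) >= cap) { capped <- TRUE; break }
      }
      if (capped) break
    }
    kcount <- length(unique(sigs))
  }
  list(n_nodes = n_nodes, n_edges = n_edges,
       edge_node_ratio = if (n_nodes > 0) n_edges / n_nodes else NA_real_,
       total_length = total, kmer_paths = kcount, capped = capped)
}

#' Write a graph as GFA 1.0
#'
#' Emits S lines for nodes, L lines for edges, and P lines for the backbone
#' and any haplotype walks.
#'
#' @param graph a [build_graph()] graph
#' @param path output file
#' @param hapindex optional [embed_haplotypes()] index
#' @export
write_gfa <- function(graph, path, hapindex = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("H\tVN:Z:1.0", con)
  writeLines(sprintf("S\t%d\t%s", graph$nodes$id, graph$nodes$seq), con)
  if (nrow(graph$edges) > 0)
    writeLines(sprintf("L\t%d\t+\t%d\t+\t0M", graph$edges$from,
                       graph$edges$to), con)
  writeLines(sprintf("P\t%s\t%s\t*", "backbone",
                     paste0(graph$backbone, "+", collapse = ",")), con)
  for (nm in names(hapindex))
    writeLines(sprintf("P\t%s\t%s\t*", nm,
                       paste0(hapindex[[nm]], "+", collapse = ",")), con)
  invisible(path)
}
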