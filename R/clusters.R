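#' Greedy identity-threshold clustering of toxin domains
#'
#' Incremental clustering in the style of classic sequence-clustering tools:
#' sequences are sorted by length (longest first, ties by id), the first
#' becomes a cluster representative, and each subsequent sequence joins the
#' first existing representative it matches at \code{>= threshold} identity
#' (\code{\link{pairwise_identity}}: identical aligned positions over the
#' shorter sequence's length). Otherwise it founds a new cluster. The
#' deterministic sort makes the partition invariant to input order, and
#' every member matches its representative at the threshold or better.
#'
#' @param domains Named character vector or \code{DNAStringSet} of domain
#'   nucleotide sequences (names are domain ids, must be unique).
#' @param threshold Identity threshold in \[0, 1\]; a member at exactly the
#'   threshold joins.
#' @return \code{data.frame}: \code{domain_id}, \code{cluster_id},
#'   \code{representative_id}, \code{is_representative},
#'   \code{identity_to_rep}; with a \code{"clusters"} attribute summarising
#'   \code{cluster_id}, \code{representative_id}, \code{size}.
#' @export
greedy_cluster <- function(domains, threshold = 0.90) {
  if (!methods::is(domains, "DNAStringSet")) {
    domains <- Biostrings::DNAStringSet(domains)
  }
  if (is.null(names(domains)) || anyDuplicated(names(domains))) {
    stop("greedy_cluster: domains must carry unique names")
  }
  n <- length(domains)
  if (n == 0L) {
    out <- data.frame(domain_id = character(0), cluster_id = character(0),
                      representative_id = character(0),
                      is_representative = logical(0),
                      identity_to_rep = numeric(0))
    attr(out, "clusters") <- data.frame(cluster_id = character(0),
                                        representative_id = character(0),
                                        size = integer(0))
    return(out)
  }
  ord <- order(-Biostrings::width(domains), names(domains))
  domains <- domains[ord]
  rep_idx <- integer(0)           # indices (into sorted set) of reps
  assign <- integer(n)            # cluster number per sorted sequence
  ident <- numeric(n)
  for (i in seq_len(n)) {
    joined <- FALSE
    if (length(rep_idx) > 0L) {
      ids <- identity_to_set(domains[rep_idx], as.character(domains[[i]]))
      hit <- which(ids >= threshold)
      if (length(hit) > 0L) {
        assign[i] <- hit[1]
        ident[i] <- ids[hit[1]]
        joined <- TRUE
      }
    }
    if (!joined) {
      rep_idx <- c(rep_idx, i)
      assign[i] <- length(rep_idx)
      ident[i] <- 1
    }
  }
  cluster_ids <- sprintf("C%03d", assign)
  rep_names <- names(domains)[rep_idx]
  out <- data.frame(domain_id = names(domains),
                    cluster_id = cluster_ids,
                    representative_id = rep_names[assign],
                    is_representative = seq_len(n) %in% rep_idx,
                    identity_to_rep = ident,
                    stringsAsFactors = FALSE)
  attr(out, "clusters") <- data.frame(
    cluster_id = sprintf("C%03d", seq_along(rep_idx)),
    representative_id = rep_names,
    size = as.integer(table(factor(assign, levels = seq_along(rep_idx)))),
    stringsAsFactors = FALSE)
  out
}

#' Build the strain-by-toxin co-occurrence network
#'
#' A bipartite graph with one node per strain and one node per toxin-domain
#' cluster; an edge connects a strain to every cluster it encodes at least
#' one member of, weighted by the member count. Strains with no domains
#' appear as isolated nodes. Strain nodes carry species/host/region labels.
#'
#' @param clustering Output of \code{\link{greedy_cluster}}.
#' @param domain_strains Named character vector mapping each
#'   \code{domain_id} to its strain id.
#' @param strain_table \code{data.frame} with columns \code{strain_id},
#'   \code{species}, \code{host}, \code{region}.
#' @return An \code{\link[igraph]{igraph}} bipartite graph (strain nodes
#'   have \code{type == FALSE}, cluster nodes \code{type == TRUE}).
#' @export
build_network <- function(clustering, domain_strains, strain_table) {
  strains <- domain_strains[clustering$domain_id]
  if (anyNA(strains)) {
    stop("build_network: domains with no strain mapping: ",
         paste(clustering$domain_id[is.na(strains)], collapse = ", "))
  }
  if (!all(strains %in% strain_table$strain_id)) {
    stop("build_network: unknown strain id(s): ",
         paste(setdiff(strains, strain_table$strain_id), collapse = ", "))
  }
  if (nrow(clustering)) {
    counts <- table(strains, clustering$cluster_id)
    el <- as.data.frame(counts, stringsAsFactors = FALSE)
    names(el) <- c("strain", "cluster", "weight")
    el <- el[el$weight > 0, , drop = FALSE]
  } else {
    el <- data.frame(strain = character(0), cluster = character(0),
                     weight = integer(0))
  }
  clusters <- sort(unique(clustering$cluster_id))
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, nrow(strain_table),
                            name = strain_table$strain_id, type = FALSE,
                            species = strain_table$species,
                            host = strain_table$host,
                            region = strain_table$region)
  if (length(clusters)) {
    g <- igraph::add_vertices(g, length(clusters), name = clusters,
                              type = TRUE, species = NA_character_,
                              host = NA_character_, region = NA_character_)
  }
  if (nrow(el)) {
    g <- igraph::add_edges(g, rbind(el$strain, el$cluster),
                           weight = el$weight)
  }
  g
}

#' Toxin-sharing summary of a co-occurrence network
#'
#' Per cluster: how many strains and species carry it, and whether it is
#' shared within a species (two or more strains of one species) or between
#' species. Globally: counts of each category and, for every pair of
#' regions, whether their strains share any toxin cluster at all.
#'
#' @param network Bipartite graph from \code{\link{build_network}}.
#' @return List with \code{per_cluster} (data.frame), \code{summary} (named
#'   counts) and \code{region_pairs} (data.frame with a \code{disjoint}
#'   flag per region pair).
#' @export
sharing_stats <- function(network) {
  v <- igraph::V(network)
  is_cluster <- v$type
  cl_names <- v$name[is_cluster]
  strain_species <- stats::setNames(v$species[!is_cluster],
                                    v$name[!is_cluster])
  strain_region <- stats::setNames(v$region[!is_cluster],
                                   v$name[!is_cluster])
  k <- length(cl_names)
  per <- data.frame(cluster_id = cl_names, n_strains = integer(k),
                    n_species = integer(k),
                    shared_within_species = logical(k),
                    shared_between_species = logical(k),
                    stringsAsFactors = FALSE)
  cluster_strains <- list()
  for (i in seq_along(cl_names)) {
    nb <- igraph::neighbors(network, cl_names[i])$name
    cluster_strains[[cl_names[i]]] <- nb
    sp <- strain_species[nb]
    per$n_strains[i] <- length(nb)
    per$n_species[i] <- length(unique(sp))
    per$shared_within_species[i] <- any(table(sp) >= 2)
    per$shared_between_species[i] <- length(unique(sp)) >= 2
  }
  summary <- c(n_clusters = nrow(per),
               shared_within_species = sum(per$shared_within_species),
               shared_between_species = sum(per$shared_between_species),
               single_strain = sum(per$n_strains == 1))
  regions <- sort(unique(stats::na.omit(strain_region)))
  region_pairs <- if (length(regions) >= 2) {
    pairs <- utils::combn(regions, 2)
    data.frame(region_a = pairs[1, ], region_b = pairs[2, ],
               disjoint = apply(pairs, 2, function(p) {
                 !any(vapply(cluster_strains, function(ss) {
                   r <- strain_region[ss]
                   p[1] %in% r && p[2] %in% r
                 }, logical(1)))
               }),
               stringsAsFactors = FALSE)
  } else {
    data.frame(region_a = character(0), region_b = character(0),
               disjoint = logical(0))
  }
  list(per_cluster = per, summary = summary, region_pairs = region_pairs)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items; 1
#' means identical partitions.
#'
#' @param a,b Label vectors of equal length.
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
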