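# Kinship graph: sparse pairwise relatedness treated as an undirected graph.
# The provider applies the 4th-degree sparsification (coefficient 2^(-9/2));
# here any positive entry is an edge.

#' Construct a kinship graph from a sparse pairwise table
#'
#' @param pairs data frame with columns `id1`, `id2`, `kin` (kinship
#'   coefficient, positive), one row per related pair; or a path to a
#'   3-column TSV.
#' @param samples character vector of all sample identifiers (isolated
#'   samples have no rows in `pairs`).
#' @return an object of class `htn_kinship`: list with `samples` and
#'   `edges` (data frame `id1`, `id2`, `kin`).
#' @export
kinship_graph <- function(pairs, samples) {
  if (is.character(pairs) && length(pairs) == 1L) {
    pairs <- as.data.frame(data.table::fread(pairs, header = TRUE))
    names(pairs)[1:3] <- c("id1", "id2", "kin")
  }
  if (is.null(pairs) || nrow(pairs) == 0L) {
    pairs <- data.frame(id1 = character(), id2 = character(),
                        kin = numeric())
  }
  stopifnot(all(c("id1", "id2", "kin") %in% names(pairs)))
  pairs <- pairs[pairs$kin > 0 & pairs$id1 != pairs$id2, , drop = FALSE]
  missing <- setdiff(unique(c(pairs$id1, pairs$id2)), samples)
  if (length(missing)) {
    stop_config("kinship references unknown samples: ",
                paste(head(missing, 5), collapse = ", "))
  }
  # canonical unordered pair, dedup keeping the first occurrence
  a <- pmin(pairs$id1, pairs$id2)
  b <- pmax(pairs$id1, pairs$id2)
  keep <- !duplicated(paste(a, b, sep = "\r"))
  structure(list(samples = as.character(samples),
                 edges = data.frame(id1 = a[keep], id2 = b[keep],
                                    kin = pairs$kin[keep],
                                    stringsAsFactors = FALSE)),
            class = "htn_kinship")
}

as_igraph <- function(k) {
  igraph::graph_from_data_frame(
    k$edges[, c("id1", "id2")], directed = FALSE,
    vertices = data.frame(name = k$samples)
  )
}

#' Partition samples into kinship-connected components
#'
#' Samples with no relatives are singleton components.  Components are the
#' atomic units for fold construction and stage splits: assigning whole
#' components keeps the subsets genetically independent.
#'
#' @param k an `htn_kinship` object.
#' @return list of character vectors, one per component, ordered by
#'   decreasing size then by first member.
#' @export
kinship_components <- function(k) {
  stopifnot(inherits(k, "htn_kinship"))
  comp <- igraph::components(as_igraph(k))
  groups <- split(names(comp$membership), comp$membership)
  groups <- lapply(groups, sort)
  ord <- order(-lengths(groups),
               vapply(groups, `[[`, "", 1L))
  unname(groups[ord])
}

#' Extract a maximal unrelated sample set
#'
#' Greedy maximal independent set: repeatedly remove the highest-degree
#' sample until no edge remains; all surviving samples are pairwise
#' unrelated.  Ties in degree are broken by a seeded shuffle, so the result
#' is deterministic given `seed`.
#'
#' @param k an `htn_kinship` object.
#' @param seed integer seed for tie-breaking.
#' @return character vector of unrelated sample ids (edge-free, verified).
#' @export
unrelated_set <- function(k, seed = 1L) {
  stopifnot(inherits(k, "htn_kinship"))
  g <- as_igraph(k)
  with_seed(seed_stream(seed, "unrelated_set"), {
    while (igraph::ecount(g) > 0) {
      deg <- igraph::degree(g)
      mx <- which(deg == max(deg))
      drop <- if (length(mx) > 1L) sample(mx, 1L) else mx
      g <- igraph::delete_vertices(g, drop)
    }
  })
  out <- igraph::V(g)$name
  # invariant: no edge inside the returned set
  inside <- k$edges$id1 %in% out & k$edges$id2 %in% out
  stopifnot(!any(inside))
  sort(out)
}

#' Sparse kinship covariance matrix for a sample subset
#'
#' Relationship matrix `2 * phi` with unit diagonal, used as the random
#' effect covariance of the logistic mixed model.
#'
#' @param k an `htn_kinship` object.
#' @param samples sample ids defining row/column order.
#' @return a sparse symmetric `Matrix::dsCMatrix`.
#' @export
kinship_matrix <- function(k, samples) {
  stopifnot(inherits(k, "htn_kinship"), all(samples %in% k$samples))
  n <- length(samples)
  idx <- setNames(seq_len(n), samples)
  e <- k$edges[k$edges$id1 %in% samples & k$edges$id2 %in% samples, ,
               drop = FALSE]
  m <- Matrix::sparseMatrix(
    i = c(seq_len(n), idx[e$id1]),
    j = c(seq_len(n), idx[e$id2]),
    x = c(rep(1, n), 2 * e$kin),
    dims = c(n, n), symmetric = TRUE
  )
  dimnames(m) <- list(samples, samples)
  m
}
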