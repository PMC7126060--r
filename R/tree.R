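# Physical tree of the sampled plant ------------------------------------------

#' Physical tree of sampled branch tips
#'
#' Wraps a rooted `ape::phylo` tree whose branch lengths are metres of
#' physical branch and whose tips are the sampled branch ends, together with
#' the mapping from each tip to its sequencing replicates. The root
#' represents the ground/germline state of the plant.
#'
#' @param phylo A rooted [ape::phylo] object with non-negative edge lengths
#'   in metres.
#' @param replicate_map Named list: tip label -> character vector of
#'   replicate sample identifiers (each tip needs at least one). If `NULL`,
#'   three replicates `<tip>.1 .. <tip>.3` are generated per tip.
#' @param n_replicates Number of auto-generated replicates per tip when
#'   `replicate_map` is `NULL`.
#' @return An object of class `physical_tree`.
#' @export
physical_tree <- function(phylo, replicate_map = NULL, n_replicates = 3) {
  stopifnot(inherits(phylo, "phylo"))
  if (!ape::is.rooted(phylo)) stop("physical tree must be rooted")
  if (is.null(phylo$edge.length)) stop("physical tree needs branch lengths (metres)")
  if (any(phylo$edge.length < 0)) stop("branch lengths must be >= 0")
  tips <- phylo$tip.label
  if (is.null(replicate_map)) {
    replicate_map <- lapply(tips, function(t) paste(t, seq_len(n_replicates), sep = "."))
    names(replicate_map) <- tips
  }
  if (!setequal(names(replicate_map), tips))
    stop("replicate_map names must match tip labels")
  if (any(vapply(replicate_map, length, 1L) < 1))
    stop("every tip needs at least one replicate")
  reps <- unlist(replicate_map, use.names = FALSE)
  if (anyDuplicated(reps)) stop("replicate identifiers must be unique")
  if (is.null(phylo$node.label) || anyNA(phylo$node.label) ||
      any(phylo$node.label == ""))
    phylo$node.label <- paste0("N", seq_len(phylo$Nnode))
  structure(list(phylo = phylo, replicate_map = replicate_map[tips]),
            class = "physical_tree")
}

#' @export
print.physical_tree <- function(x, ...) {
  cat(sprintf("physical_tree: %d tips, %d edges, %.1f m total branch length\n",
              length(x$phylo$tip.label), nrow(x$phylo$edge),
              sum(x$phylo$edge.length)))
  rng <- range(leaf_path_lengths(x))
  cat(sprintf("  root-to-tip path lengths: %.1f - %.1f m\n", rng[1], rng[2]))
  cat(sprintf("  replicates: %d (%s per tip)\n",
              length(replicates(x)),
              paste(unique(vapply(x$replicate_map, length, 1L)), collapse = "/")))
  invisible(x)
}

#' Replicate sample table of a physical tree
#'
#' @param tree A [physical_tree()].
#' @return `data.frame` with columns `replicate` and `leaf`, in canonical
#'   order (tips in tip-label order, replicates within tip).
#' @export
replicate_table <- function(tree) {
  data.frame(
    replicate = unlist(tree$replicate_map, use.names = FALSE),
    leaf = rep(names(tree$replicate_map),
               vapply(tree$replicate_map, length, 1L)),
    stringsAsFactors = FALSE)
}

replicates <- function(tree) replicate_table(tree)$replicate

#' Root-to-tip physical path lengths
#'
#' @param tree A [physical_tree()].
#' @return Named numeric vector, metres from the root to each tip.
#' @export
leaf_path_lengths <- function(tree) {
  d <- ape::node.depth.edgelength(tree$phylo)
  n_tip <- length(tree$phylo$tip.label)
  stats::setNames(d[seq_len(n_tip)], tree$phylo$tip.label)
}

#' Total physical branch length
#'
#' @param tree A [physical_tree()].
#' @return Sum of all edge lengths, metres.
#' @export
total_branch_length <- function(tree) sum(tree$phylo$edge.length)

node_label <- function(phylo, node) {
  n_tip <- length(phylo$tip.label)
  out <- character(length(node))
  tip <- node <= n_tip
  out[tip] <- phylo$tip.label[node[tip]]
  out[!tip] <- phylo$node.label[node[!tip] - n_tip]
  out
}

#' Edge table of a physical tree
#'
#' @param tree A [physical_tree()].
#' @return `data.frame` with one row per edge: `edge` (the `"parent->child"`
#'   name used in calls and spike plans), `parent`, `child`, `length_m`.
#' @export
edge_table <- function(tree) {
  ph <- tree$phylo
  parent <- node_label(ph, ph$edge[, 1])
  child <- node_label(ph, ph$edge[, 2])
  data.frame(edge = paste0(parent, "->", child), parent = parent,
             child = child, length_m = ph$edge.length,
             stringsAsFactors = FALSE)
}

# list over edges (rows of phylo$edge) of tip labels below each edge
edge_descendant_tips <- function(tree) {
  ph <- tree$phylo
  n_tip <- length(ph$tip.label)
  desc <- phangorn::Descendants(ph, ph$edge[, 2], type = "tips")
  lapply(desc, function(i) ph$tip.label[i])
}

#' Expand a physical tree to its replicate (per-sample) tree
#'
#' Replaces every tip by a resolved binary subtree of its replicate samples
#' joined by zero-length edges, as the tree that genotyping software sees
#' when every replicate enters as a separate sample (24 taxa for 8 tips
#' with 3 replicates).
#'
#' @param tree A [physical_tree()].
#' @return An [ape::phylo] with one tip per replicate sample.
#' @export
replicate_tree <- function(tree) {
  ph <- tree$phylo
  out <- ph
  for (tip in ph$tip.label) {
    reps <- tree$replicate_map[[tip]]
    if (length(reps) == 1) {
      out$tip.label[out$tip.label == tip] <- reps
      next
    }
    sub <- ape::stree(length(reps), type = "left")  # caterpillar, binary
    sub$tip.label <- reps
    sub$edge.length <- rep(0, nrow(sub$edge))
    where <- which(out$tip.label == tip)
    out <- ape::bind.tree(out, sub, where = where)
  }
  out
}

#' Default physical tree emulating the studied eucalypt
#'
#' A stylised eight-tip physical tree with 14 edges: total branch length
#' 90.1 m, root-to-tip paths spanning 8.4 to 20.3 m, and the
#' herbivory-relevant clade \{M1, M2, M3\} subtended by the internal edge
#' B->C. Exact per-edge lengths are a choice satisfying those constraints;
#' tips carry three replicates each (`M1.1` ... `M8.3`).
#'
#' @return A [physical_tree()] with 8 tips and 24 replicates.
#' @export
default_fig1_tree <- function() {
  nwk <- paste0(
    "((((M1:12.8,M2:7.1)D:2.0,M3:6.0)C:2.5,(M4:11.0,M5:13.3)E:4.0)B:3.0,",
    "(M6:3.4,(M7:9.0,M8:7.0)G:4.0)F:5.0)A;")
  ph <- ape::read.tree(text = nwk)
  physical_tree(ph)
}

#' Read a physical tree from Newick plus a replicate sample map
#'
#' @param newick_path Path to a Newick file with branch lengths in metres.
#' @param sample_map_path Path to a two-column TSV (`replicate`, `leaf`)
#'   mapping replicate sample identifiers to tip labels. Optional; three
#'   replicates per tip are generated when absent.
#' @return A [physical_tree()].
#' @export
read_physical_tree <- function(newick_path, sample_map_path = NULL) {
  ph <- ape::read.tree(newick_path)
  rmap <- NULL
  if (!is.null(sample_map_path)) {
    sm <- utils::read.table(sample_map_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    stopifnot(all(c("replicate", "leaf") %in% names(sm)))
    rmap <- split(sm$replicate, sm$leaf)
  }
  physical_tree(ph, replicate_map = rmap)
}

#' Write a physical tree as Newick plus a replicate sample map
#'
#' @param tree A [physical_tree()].
#' @param newick_path,sample_map_path Output paths (TSV map skipped if
#'   `NULL`).
#' @return Invisibly, the tree.
#' @export
write_physical_tree <- function(tree, newick_path, sample_map_path = NULL) {
  ape::write.tree(tree$phylo, file = newick_path)
  if (!is.null(sample_map_path))
    utils::write.table(replicate_table(tree), sample_map_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(tree)
}
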