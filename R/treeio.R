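## Tree and trait I/O built on ape's "phylo" container.  Trees are used
## exactly as read: rooted as written, polytomies preserved, no rerooting.

#' Parse a Newick string into a validated rooted tree
#'
#' Wraps [ape::read.tree()] with structural pre-checks that report the
#' character offset of common syntax errors, then validates the result
#' (unique leaf names, nonnegative branch lengths, single root).  Missing
#' branch lengths are filled with 1.0 and a warning, so likelihood
#' computation stays possible on consensus trees that omit them; zero
#' lengths are kept as exact zeros.  Internal node labels (e.g. posterior
#' supports) are retained but never used in computation.
#'
#' @param text A single Newick string (must end in `;`).
#' @return An object of class `phylo`.
#' @export
parse_newick <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("`text` must be a single Newick string")
  }
  .newick_syntax_check(text)
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e), call. = FALSE),
    warning = function(w) stop("Newick parse error: ", conditionMessage(w), call. = FALSE)
  )
  if (is.null(tree)) stop("Newick parse error: unparseable string")
  validate_tree(tree)
}

# Cheap scan for unbalanced parentheses / missing terminator, reporting a
# 1-based character offset (ape's own errors do not carry positions).
.newick_syntax_check <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop(sprintf("Newick parse error at character %d: unmatched ')'", i))
      }
    }
  }
  if (depth > 0L) {
    stop(sprintf("Newick parse error at character %d: %d unclosed '('",
                 length(chars), depth))
  }
  if (!grepl(";", text, fixed = TRUE)) {
    stop(sprintf("Newick parse error at character %d: missing ';' terminator",
                 length(chars)))
  }
  invisible(TRUE)
}

#' Validate a phylo object against the package's tree invariants
#'
#' @param tree A `phylo` object.
#' @return The tree, invisibly repaired (missing branch lengths set to 1
#'   with a warning).
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("`tree` must be a phylo object")
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop("duplicate leaf names: ", paste(dup, collapse = ", "))
  }
  n_total <- length(tree$tip.label) + tree$Nnode
  parent_count <- tabulate(tree$edge[, 2], nbins = n_total)
  if (any(parent_count > 1L)) stop("node with more than one parent")
  roots <- setdiff(tree$edge[, 1], tree$edge[, 2])
  if (length(unique(roots)) != 1L) stop("tree must have exactly one root")
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; defaulting all to 1.0")
    tree$edge.length <- rep(1.0, nrow(tree$edge))
  } else if (anyNA(tree$edge.length)) {
    warning("missing branch lengths on ", sum(is.na(tree$edge.length)),
            " edge(s); defaulting to 1.0")
    tree$edge.length[is.na(tree$edge.length)] <- 1.0
  }
  if (any(tree$edge.length < 0)) stop("negative branch length")
  tree
}

#' Write a tree as a Newick string
#'
#' Branch lengths are written with 10 significant digits so that
#' parse -> write -> parse round-trips exactly at that precision.
#'
#' @param tree A `phylo` object.
#' @param file Optional path; when `NULL` the string is returned.
#' @return The Newick string (invisibly when writing to a file).
#' @export
write_newick <- function(tree, file = NULL) {
  txt <- ape::write.tree(tree, digits = 10)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Read one or more Newick trees from a file
#'
#' Multi-tree files carry one Newick string per line (a posterior tree
#' sample, for instance).
#'
#' @param file Path to a Newick file.
#' @return A single `phylo` when the file holds one tree, otherwise a list
#'   of `phylo` objects.
#' @export
read_newick <- function(file) {
  lines <- trimws(readLines(file))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("no Newick strings in ", file)
  trees <- lapply(lines, parse_newick)
  if (length(trees) == 1L) trees[[1]] else trees
}

#' Trait data: taxon -> phenotype state
#'
#' Constructs the trait container used throughout the package: an integer
#' state index per taxon plus an ordered state alphabet (default
#' `c("CI","FI","MK","O","PI")`).
#'
#' @param states Named character vector of state labels (names = taxa), or
#'   named integer vector of 1-based state indices.
#' @param alphabet Ordered character vector of state labels.
#' @return An object of class `trait_data` with fields `index` (named
#'   integer vector) and `alphabet`.
#' @export
trait_data <- function(states, alphabet = default_alphabet()) {
  if (is.null(names(states)) || any(!nzchar(names(states)))) {
    stop("`states` must be named by taxon")
  }
  if (anyDuplicated(names(states))) {
    stop("duplicate taxon: ",
         paste(unique(names(states)[duplicated(names(states))]), collapse = ", "))
  }
  if (anyDuplicated(alphabet)) stop("alphabet labels must be unique")
  if (is.character(states) || is.factor(states)) {
    idx <- match(as.character(states), alphabet)
    if (anyNA(idx)) {
      bad <- which(is.na(idx))[1]
      stop(sprintf("phenotype label '%s' (taxon '%s') not in alphabet [%s]",
                   as.character(states)[bad], names(states)[bad],
                   paste(alphabet, collapse = ", ")))
    }
  } else {
    idx <- as.integer(states)
    if (any(idx < 1L) || any(idx > length(alphabet))) {
      stop("state index outside alphabet")
    }
  }
  structure(list(index = setNames(idx, names(states)), alphabet = alphabet),
            class = "trait_data")
}

#' @export
print.trait_data <- function(x, ...) {
  cat("trait_data:", length(x$index), "taxa,",
      length(x$alphabet), "states (", paste(x$alphabet, collapse = " "), ")\n")
  tab <- table(factor(x$alphabet[x$index], levels = x$alphabet))
  print(tab)
  invisible(x)
}

#' Read a tab-separated trait table
#'
#' Expects a UTF-8 TSV with a header line `taxon<TAB>phenotype`.
#'
#' @param file Path or connection.
#' @param alphabet State alphabet; rows with labels outside it are rejected.
#' @return A [trait_data] object.
#' @export
read_trait_table <- function(file, alphabet = default_alphabet()) {
  df <- read.delim(file, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   colClasses = "character", fileEncoding = "UTF-8")
  need <- c("taxon", "phenotype")
  if (!all(need %in% names(df))) {
    stop("trait table must have columns 'taxon' and 'phenotype' (found: ",
         paste(names(df), collapse = ", "), ")")
  }
  if (anyDuplicated(df$taxon)) {
    stop("duplicate taxon rows: ",
         paste(unique(df$taxon[duplicated(df$taxon)]), collapse = ", "))
  }
  bad <- which(!(df$phenotype %in% alphabet))
  if (length(bad)) {
    stop(sprintf("row %d: phenotype '%s' (taxon '%s') not in alphabet [%s]",
                 bad[1], df$phenotype[bad[1]], df$taxon[bad[1]],
                 paste(alphabet, collapse = ", ")))
  }
  trait_data(setNames(df$phenotype, df$taxon), alphabet = alphabet)
}

#' Write a trait table as TSV
#'
#' @param traits A [trait_data] object.
#' @param file Output path.
#' @export
write_trait_table <- function(traits, file) {
  df <- data.frame(taxon = names(traits$index),
                   phenotype = traits$alphabet[traits$index],
                   stringsAsFactors = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

# Tree/trait compatibility: leaf-name sets must match exactly (outgroup
# included).  Returns tip states as a 0-based integer vector in tip order.
check_tree_traits <- function(tree, traits) {
  stopifnot(inherits(tree, "phylo"), inherits(traits, "trait_data"))
  missing_t <- setdiff(tree$tip.label, names(traits$index))
  extra_t <- setdiff(names(traits$index), tree$tip.label)
  if (length(missing_t) || length(extra_t)) {
    stop("tree/trait leaf sets differ",
         if (length(missing_t)) paste0("; no trait for: ", paste(head(missing_t, 5), collapse = ", ")),
         if (length(extra_t)) paste0("; not in tree: ", paste(head(extra_t, 5), collapse = ", ")))
  }
  as.integer(traits$index[tree$tip.label]) - 1L
}

#' Collapse a tree to a star tree
#'
#' Returns a tree with the same leaf set whose root is the only internal
#' node, destroying all phylogenetic structure.  Each pendant branch gets
#' the mean root-to-leaf path length of the source tree (override with
#' `pendant_length`), so trait change per lineage stays on a comparable
#' scale between the star and the original tree.
#'
#' @param tree A `phylo` object with >= 2 leaves.
#' @param pendant_length Optional fixed pendant branch length.
#' @return A star-shaped `phylo`.
#' @export
make_star_tree <- function(tree, pendant_length = NULL) {
  tree <- validate_tree(tree)
  n <- length(tree$tip.label)
  if (n < 2L) stop("star tree needs >= 2 leaves")
  if (is.null(pendant_length)) {
    depths <- ape::node.depth.edgelength(tree)[seq_len(n)]
    if (all(depths == 0)) stop("all root-to-leaf path lengths are zero; star tree degenerate")
    pendant_length <- mean(depths)
  }
  star <- list(
    edge = cbind(rep(n + 1L, n), seq_len(n)),
    edge.length = rep(pendant_length, n),
    tip.label = tree$tip.label,
    Nnode = 1L
  )
  class(star) <- "phylo"
  attr(star, "order") <- "cladewise"
  star
}

#' Most recent common ancestor of a set of leaves
#'
#' @param tree A `phylo` object.
#' @param taxa Nonempty character vector of leaf names.
#' @return Integer node id (ape convention: tips `1..n`, root `n+1`).
#' @export
mrca_node <- function(tree, taxa) {
  if (length(taxa) == 0L) stop("`taxa` must be nonempty")
  hit <- match(taxa, tree$tip.label)
  if (anyNA(hit)) {
    stop("unknown taxa: ", paste(taxa[is.na(hit)], collapse = ", "))
  }
  if (length(hit) == 1L) return(hit)
  ape::getMRCA(tree, unique(hit))
}

# Postorder edge encoding consumed by the C++ kernels.
encode_tree <- function(tree) {
  tree <- validate_tree(tree)
  post <- ape::reorder.phylo(tree, "postorder")
  list(
    edge = matrix(as.integer(post$edge), ncol = 2),
    elen = as.numeric(post$edge.length),
    ntip = length(tree$tip.label),
    nnode = tree$Nnode
  )
}
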