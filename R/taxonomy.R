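#' Load an NCBI-style taxonomy from nodes/names dump files
#'
#' Parses the NCBI taxdump dialect: fields separated by `"\t|\t"`, records
#' terminated by `"\t|"`.  Columns 1-3 of the nodes file are taxid, parent
#' taxid and rank; rows of the names file whose name class is
#' `"scientific name"` supply the scientific names.  Nodes without a
#' scientific name are named `"taxid:<id>"`.
#'
#' @param nodes_path Path to a `nodes.dmp`-style file.
#' @param names_path Path to a `names.dmp`-style file.
#' @return An object of class `taxonomy_tree` with named-vector fields
#'   `parent`, `rank` and `name` (names are taxids as character) and the
#'   `root` taxid.  The root is the unique node whose parent is itself.
#' @export
load_taxonomy <- function(nodes_path, names_path) {
  nodes <- parse_dmp(nodes_path)
  if (!length(nodes)) stop("empty nodes file: ", nodes_path)
  taxid <- vapply(nodes, `[`, "", 1)
  parent <- vapply(nodes, `[`, "", 2)
  rank <- vapply(nodes, `[`, "", 3)
  if (anyDuplicated(taxid))
    stop("duplicate taxid in nodes file: ", taxid[duplicated(taxid)][1])
  missing_parent <- setdiff(parent, taxid)
  if (length(missing_parent))
    stop("parent taxid not present in nodes file: ",
         paste(utils::head(missing_parent, 10), collapse = ", "))
  root <- taxid[parent == taxid]
  if (length(root) != 1)
    stop("expected exactly one root (parent == self), found ", length(root))

  # cycle check: walking up from every node must reach the root
  parent_map <- setNames(parent, taxid)
  depth <- setNames(rep(NA_integer_, length(taxid)), taxid)
  depth[root] <- 0L
  for (t in taxid) {
    chain <- character(0)
    cur <- t
    while (is.na(depth[cur])) {
      if (cur %in% chain)
        stop("cycle detected in taxonomy involving taxid ", cur)
      chain <- c(chain, cur)
      cur <- parent_map[[cur]]
    }
    if (length(chain))
      depth[chain] <- depth[[cur]] + rev(seq_along(chain))
  }

  nm <- setNames(paste0("taxid:", taxid), taxid)
  names_rows <- parse_dmp(names_path)
  for (row in names_rows) {
    if (length(row) >= 4 && trimws(row[4]) == "scientific name" &&
        row[1] %in% taxid)
      nm[[row[1]]] <- trimws(row[2])
  }

  structure(list(parent = parent_map,
                 rank = setNames(rank, taxid),
                 name = nm,
                 root = root),
            class = "taxonomy_tree")
}

# Parse one NCBI dump file into a list of character field vectors.
parse_dmp <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lines <- sub("\t\\|$", "", lines)
  strsplit(lines, "\t\\|\t", fixed = FALSE)
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat(sprintf("<taxonomy_tree> %d taxa, root %s\n", length(x$parent), x$root))
  invisible(x)
}

#' Project a taxon to its ancestor at a named rank
#'
#' Walks parent links from `taxon` (starting at the taxon itself) until a
#' node with the requested rank is found.  Intermediate ranks outside the
#' six accepted ones are traversed silently.
#'
#' @param tree A [load_taxonomy()] tree.
#' @param taxon A taxid present in the tree (coerced to character).
#' @param rank One of `"species"`, `"genus"`, `"family"`, `"order"`,
#'   `"class"`, `"phylum"`.
#' @return The ancestor taxid as an integer, or `NA` if the lineage has no
#'   node of that rank.
#' @export
ancestor_at_rank <- function(tree, taxon, rank) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  if (!rank %in% RANKS)
    stop("unknown rank '", rank, "'; accepted ranks: ",
         paste(RANKS, collapse = ", "))
  cur <- as.character(taxon)
  if (!cur %in% names(tree$parent)) stop("unknown taxon: ", taxon)
  repeat {
    if (identical(unname(tree$rank[[cur]]), rank))
      return(as.integer(cur))
    p <- tree$parent[[cur]]
    if (p == cur) return(NA_integer_)
    cur <- p
  }
}

# Vectorized rank projection over many taxids.
taxa_at_rank <- function(tree, taxa, rank) {
  vapply(taxa, function(t) ancestor_at_rank(tree, t, rank), integer(1))
}

#' Read an accession-to-taxid mapping file
#'
#' Two tab-separated columns, `accession<TAB>taxid`, with an optional
#' header line.
#'
#' @param path Path to the mapping file.
#' @param tree Optional [load_taxonomy()] tree; when given, every taxid must
#'   exist in the tree.
#' @return A named integer vector mapping accession to taxid.
#' @export
read_taxmap <- function(path, tree = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.table(path, sep = "\t", header = FALSE,
                    colClasses = "character", quote = "")
  if (ncol(tab) < 2) stop("taxmap must have two tab-separated columns")
  if (nrow(tab) && is.na(suppressWarnings(as.integer(tab[1, 2]))))
    tab <- tab[-1, , drop = FALSE]  # header line
  taxmap <- setNames(as.integer(tab[[2]]), tab[[1]])
  if (any(is.na(taxmap))) stop("non-integer taxid in taxmap")
  if (!is.null(tree)) validate_taxmap(taxmap, tree)
  taxmap
}

validate_taxmap <- function(taxmap, tree) {
  bad <- unique(as.character(taxmap[!as.character(taxmap) %in%
                                      names(tree$parent)]))
  if (length(bad))
    stop("taxid(s) absent from taxonomy: ",
         paste(utils::head(bad, 10), collapse = ", "))
  invisible(taxmap)
}

#' Write an accession-to-taxid mapping file
#' @param taxmap Named integer vector (names are accessions).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxmap <- function(taxmap, path) {
  write.table(data.frame(accession = names(taxmap), taxid = unname(taxmap)),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
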