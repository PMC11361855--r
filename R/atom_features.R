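# Atom-level model inputs: node one-hot features and the Bond / Graph /
# Conf pairwise matrices with inverse-distance attenuation.

NODE_FEATURE_WIDTH <- 30L

# one-hot vocabularies; out-of-vocabulary values fall into the last
# ("other") slot of each block
ATOM_TYPES <- c("C", "N", "O", "S", "F", "Cl", "Br")   # + other = 8
DEGREES <- c(1L, 2L, 3L, 4L)                           # + other = 5
H_COUNTS <- 0:4                                        # 5 (>=5 folds to 4)
CHARGES <- c(-1L, 0L, 1L)                              # + other = 4
HYBRIDIZATIONS <- c("sp", "sp2")                       # + sp3/other = 3
CHIRALITIES <- c("none", "cw", "ccw")                  # 3

one_hot <- function(value, vocab, other = TRUE) {
  n <- length(vocab) + as.integer(other)
  v <- numeric(n)
  i <- match(value, vocab)
  if (is.na(i)) {
    if (!other) i <- n else i <- n  # fold into the trailing slot
  }
  v[i] <- 1
  v
}

#' Per-atom node feature matrix
#'
#' Encodes each heavy atom as a 30-wide row of six one-hot blocks (atom
#' type 8, heavy-atom degree 5, bonded hydrogens 5, formal charge 4,
#' hybridization 3, chirality 3) plus two boolean flags (in ring,
#' aromatic).  Out-of-vocabulary values occupy each block's final slot;
#' hydrogen counts above 4 are folded into the 4 slot.
#'
#' @param mol A parsed molecule: either a `peptide_record` or a SMILES
#'   string.
#' @return N x 30 numeric matrix (N heavy atoms).
#' @export
node_features <- function(mol) {
  at <- atom_tables(mol)$atoms
  n <- length(at$symbol)
  out <- matrix(0, n, NODE_FEATURE_WIDTH)
  for (i in seq_len(n)) {
    out[i, ] <- c(
      one_hot(at$symbol[i], ATOM_TYPES),
      one_hot(at$degree[i], DEGREES),
      one_hot(min(at$num_h[i], 4L), H_COUNTS, other = FALSE),
      one_hot(at$charge[i], CHARGES),
      one_hot(at$hybridization[i], HYBRIDIZATIONS),
      one_hot(at$chirality[i], CHIRALITIES, other = FALSE),
      at$in_ring[i],
      at$aromatic[i]
    )
  }
  out
}

#' Bond weight matrix
#'
#' Symmetric N x N matrix of bonded-pair weights: aromatic 1.5, triple 3.0,
#' double 2.0, conjugated single 1.4, plain single 1.0; non-bonded pairs
#' and the diagonal are 0.  Conjugation upgrades only single bonds;
#' aromatic, double and triple bonds keep their order weights.
#'
#' @inheritParams node_features
#' @return N x N numeric matrix.
#' @export
bond_matrix <- function(mol) {
  tb <- atom_tables(mol)
  n <- length(tb$atoms$symbol)
  out <- matrix(0, n, n)
  b <- tb$bonds
  for (k in seq_along(b$i)) {
    i <- b$i[k] + 1L
    j <- b$j[k] + 1L
    w <- if (b$aromatic[k] == 1) 1.5
    else if (b$order[k] == 3) 3.0
    else if (b$order[k] == 2) 2.0
    else if (b$conjugated[k] == 1) 1.4
    else 1.0
    out[i, j] <- w
    out[j, i] <- w
  }
  out
}

#' Graph distance matrix
#'
#' All-pairs shortest path lengths on the heavy-atom bond graph.
#'
#' @inheritParams node_features
#' @return Symmetric integer-valued N x N matrix with zero diagonal.
#' @export
graph_distance_matrix <- function(mol) {
  tb <- atom_tables(mol)
  n <- length(tb$atoms$symbol)
  if (length(tb$bonds$i) == 0) {
    if (n == 1) return(matrix(0, 1, 1))
    input_error("molecule has no bonds")
  }
  g <- igraph::graph_from_edgelist(
    cbind(tb$bonds$i + 1L, tb$bonds$j + 1L), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  d <- igraph::distances(g)
  if (any(is.infinite(d))) input_error("disconnected molecule")
  unname(d)
}

#' Euclidean distance matrix from 3D coordinates
#'
#' @param coordinates N x 3 matrix of heavy-atom coordinates (Angstrom).
#' @return Symmetric N x N matrix of pairwise distances.
#' @export
conf_distance_matrix <- function(coordinates) {
  coordinates <- as_coord_matrix(coordinates)
  if (!all(is.finite(coordinates))) input_error("non-finite coordinates")
  d <- as.matrix(stats::dist(coordinates))
  dimnames(d) <- NULL
  d
}

#' Inverse-distance attenuation (Strength matrix)
#'
#' Maps a pairwise distance matrix to attention attenuation weights: 1 on
#' the diagonal, `1/distance` off-diagonal, clipped to at most 1 so that
#' sub-Angstrom 3D contacts cannot amplify attention.  Rows and columns
#' flagged as padding are zeroed.
#'
#' @param distance Symmetric nonnegative matrix with zero diagonal.
#' @param mask Logical vector, `TRUE` for real atoms (default all real).
#' @return Matrix of the same shape with entries in `[0, 1]`.
#' @export
attenuation <- function(distance, mask = NULL) {
  n <- nrow(distance)
  if (is.null(mask)) mask <- rep(TRUE, n)
  off <- distance[row(distance) != col(distance) & outer(mask, mask, "&")]
  if (any(off == 0)) {
    pepperm_error("pepperm_degeneracy_error",
                  "zero off-diagonal distance between distinct real atoms")
  }
  s <- 1 / distance
  s[!is.finite(s)] <- 0
  s <- pmin(s, 1)
  diag(s) <- 1
  s[!mask, ] <- 0
  s[, !mask] <- 0
  diag(s)[!mask] <- 0
  s
}

#' Assemble the padded atom feature set
#'
#' Bundles the node matrix, Bond weights, graph and 3D distances and their
#' attenuated Strength matrices, padded to `n_max` rows/columns with a
#' logical mask marking real atoms.
#'
#' @inheritParams node_features
#' @param coordinates N x 3 heavy-atom coordinates for the Conf matrix.
#' @param n_max Padding size (default 128).
#' @return An object of class `atom_feature_set` with fields `node`,
#'   `bond`, `graph`, `conf`, `strength_graph`, `strength_conf`, `mask`,
#'   `n_real`.
#' @export
atom_feature_set <- function(mol, coordinates, n_max = 128) {
  node <- node_features(mol)
  n <- nrow(node)
  if (n > n_max) size_error(sprintf("%d atoms exceed padding size %d", n, n_max))
  bond <- bond_matrix(mol)
  graph <- graph_distance_matrix(mol)
  conf <- conf_distance_matrix(coordinates)
  if (nrow(conf) != n) input_error("coordinates do not match heavy-atom count")
  mask <- c(rep(TRUE, n), rep(FALSE, n_max - n))
  pad_mat <- function(m) {
    out <- matrix(0, n_max, n_max)
    out[1:n, 1:n] <- m
    out
  }
  pad_rows <- function(m) {
    out <- matrix(0, n_max, ncol(m))
    out[1:n, ] <- m
    out
  }
  sg <- pad_mat(attenuation(graph))
  sc <- pad_mat(attenuation(conf))
  structure(
    list(node = pad_rows(node), bond = pad_mat(bond), graph = pad_mat(graph),
         conf = pad_mat(conf), strength_graph = sg, strength_conf = sc,
         mask = mask, n_real = n),
    class = "atom_feature_set"
  )
}

# molecule-to-tables cache: accepts a peptide_record, a SMILES string, or a
# pre-fetched backend parse result
atom_tables <- function(mol) {
  if (is.list(mol) && !is.null(mol$atoms) && !is.null(mol$bonds)) {
    return(mol)
  }
  smiles <- if (inherits(mol, "peptide_record")) mol$smiles else mol
  res <- run_backend("parse", list(jobs = list(list(id = "x", smiles = smiles))))
  r <- res$results[[1]]
  if (!isTRUE(r$ok)) input_error(r$error)
  r
}
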