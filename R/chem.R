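#' Atom feature encoding scheme
#'
#' Five per-atom descriptors are encoded into a fixed-width numeric row:
#' element symbol as a one-hot over a fixed vocabulary of common drug elements
#' plus an "other" slot; heavy-atom degree, implicit valence and attached
#' hydrogen count as capped one-hots over 0..5 with an overflow bucket; and a
#' single aromaticity flag. The total width is constant across molecules.
#'
#' @return A list with the element vocabulary (`elements`), the cap for count
#'   one-hots (`count_cap`), the per-block widths (`widths`) and the total
#'   feature width (`width`).
#' @export
#' @examples
#' atom_feature_info()$width
atom_feature_info <- function() {
  elements <- c("C", "N", "O", "S", "F", "Cl", "Br", "I", "P", "B")
  count_cap <- 5L
  widths <- c(
    symbol = length(elements) + 1L,
    degree = count_cap + 2L,
    implicit_valence = count_cap + 2L,
    hydrogens = count_cap + 2L,
    aromatic = 1L
  )
  list(elements = elements, count_cap = count_cap,
       widths = widths, width = sum(widths))
}

# Standard bonding valences used when ChemmineR's per-atom bond summary is
# unavailable (molecules with no bonds). Matches ChemmineR's internal rules
# for the supported vocabulary.
.default_valence <- c(C = 4, N = 3, O = 2, S = 2, F = 1, Cl = 1, Br = 1,
                      I = 1, P = 3, B = 3, H = 1)

one_hot <- function(index, width) {
  v <- numeric(width)
  v[index] <- 1
  v
}

# Capped count one-hot: slots for 0..cap plus one overflow slot.
count_one_hot <- function(count, cap) {
  one_hot(min(count, cap + 1L) + 1L, cap + 2L)
}

#' Convert a SMILES string to a molecular graph
#'
#' Parses one SMILES string into a heavy-atom graph: nodes are non-hydrogen
#' atoms in the parser's output order (stable for a fixed input), edges are
#' covalent bonds, hydrogens are implicit and contribute only to the
#' per-atom hydrogen-count descriptor. Aromaticity is the ring-perception
#' flag of the parser: an atom is aromatic when it belongs to at least one
#' aromatic ring.
#'
#' @param smiles A single non-empty SMILES string.
#' @param featurize If `TRUE` (default) the node feature matrix is attached
#'   (see [featurize_atoms()]).
#' @return An object of class `molecular_graph`: a list with `smiles`,
#'   `num_atoms`, `atom_symbols`, `edges` (two-column integer matrix of
#'   unordered bonds, zero rows when there are none), `bond_orders`,
#'   `degree`, `n_hydrogens`, `implicit_valence`, `aromatic` (logical per
#'   atom) and, when requested, `node_features`.
#' @export
#' @examples
#' g <- smiles_to_graph("CCO")
#' g$num_atoms  # 3 heavy atoms
#' nrow(g$edges)  # 2 bonds
smiles_to_graph <- function(smiles, featurize = TRUE) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(trimws(smiles)))
    stop("'smiles' must be a single non-empty SMILES string", call. = FALSE)
  smiles <- trimws(smiles)

  # Bond-less molecules (a single heavy atom) break ChemmineR's SDF
  # container, so that degenerate case is parsed directly from the SMILES.
  single <- .parse_single_atom_smiles(smiles)
  if (!is.null(single)) {
    g <- structure(c(list(smiles = smiles), single,
                     class = NULL), class = "molecular_graph")
    if (featurize) g$node_features <- featurize_atoms(g)
    return(g)
  }

  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e)
      stop(sprintf("cannot parse SMILES %s: %s", deparse(smiles),
                   conditionMessage(e)), call. = FALSE)
  )
  sdf <- sdf[[1]]
  ab <- ChemmineR::atomblock(sdf)
  if (is.null(ab) || nrow(ab) == 0L || all(grepl("^[0-9]+$", rownames(ab))))
    stop(sprintf("cannot parse SMILES %s: no atoms returned", deparse(smiles)),
         call. = FALSE)

  symbols <- sub("_[0-9]+$", "", rownames(ab))
  n <- length(symbols)

  bb <- tryCatch(ChemmineR::bondblock(sdf), error = function(e) NULL)
  if (is.null(bb) || length(bb) == 0L || nrow(bb) == 0L || ncol(bb) < 3L ||
      all(bb[, 1:2] == 0)) {
    edges <- matrix(integer(0), ncol = 2L,
                    dimnames = list(NULL, c("from", "to")))
    orders <- integer(0)
  } else {
    bb <- matrix(as.integer(bb[, 1:3, drop = FALSE]), ncol = 3L)
    edges <- cbind(from = pmin(bb[, 1L], bb[, 2L]),
                   to   = pmax(bb[, 1L], bb[, 2L]))
    orders <- bb[, 3L]
    dup <- duplicated(edges)
    edges <- edges[!dup, , drop = FALSE]
    orders <- orders[!dup]
    if (any(edges < 1L | edges > n))
      stop(sprintf("cannot parse SMILES %s: bond references a missing atom",
                   deparse(smiles)), call. = FALSE)
  }

  degree <- tabulate(c(edges), nbins = n)

  # Bond-order sum, standard valence and formal charge per atom; for
  # bond-less molecules fall back to the valence table (neutral atoms).
  if (nrow(edges) > 0L) {
    binfo <- ChemmineR::bonds(sdf, type = "bonds")
    order_sum <- binfo$Nbondcount
    valence_rule <- binfo$Nbondrule
    charge <- binfo$charge
  } else {
    order_sum <- rep(0L, n)
    valence_rule <- unname(.default_valence[symbols])
    valence_rule[is.na(valence_rule)] <- 0L
    charge <- rep(0L, n)
  }
  n_h <- pmax(0L, valence_rule + charge - order_sum)

  aromatic <- rep(FALSE, n)
  if (nrow(edges) > 0L) {
    rg <- tryCatch(
      suppressWarnings(ChemmineR::rings(sdf, type = "all", arom = TRUE)),
      error = function(e) NULL)
    if (!is.null(rg) && length(rg$RINGS) > 0L) {
      arom_atoms <- unique(unlist(rg$RINGS[rg$AROMATIC], use.names = FALSE))
      idx <- as.integer(sub("^.*_", "", arom_atoms))
      aromatic[idx[idx >= 1L & idx <= n]] <- TRUE
    }
  }

  g <- structure(list(
    smiles = smiles,
    num_atoms = n,
    atom_symbols = symbols,
    edges = edges,
    bond_orders = orders,
    degree = degree,
    n_hydrogens = as.integer(n_h),
    implicit_valence = as.integer(n_h),  # H are implicit, so the two coincide
    aromatic = aromatic
  ), class = "molecular_graph")
  if (featurize) g$node_features <- featurize_atoms(g)
  g
}

# Recognize a SMILES that denotes exactly one heavy atom, e.g. "C", "O",
# "[NH4+]", "[Cl-]". Returns NULL when the SMILES is anything larger.
.parse_single_atom_smiles <- function(smiles) {
  m <- regmatches(smiles, regexec(
    "^(?:(Br|Cl|B|C|N|O|P|S|F|I)|\\[([A-Z][a-z]?)(H([0-9]*))?(([+-])([0-9]*))?\\])$",
    smiles))[[1]]
  if (length(m) == 0L) return(NULL)
  bare <- m[2]; bracket <- m[3]
  sym <- if (nzchar(bare)) bare else bracket
  charge <- 0L
  if (nzchar(m[6])) {
    mag <- if (nzchar(m[8])) as.integer(m[8]) else 1L
    charge <- if (m[7] == "-") -mag else mag
  }
  if (nzchar(m[4])) {
    n_h <- if (nzchar(m[5])) as.integer(m[5]) else 1L
  } else if (nzchar(bare)) {
    n_h <- max(0L, unname(.default_valence[sym]) + charge)
    if (is.na(n_h)) n_h <- 0L
  } else n_h <- 0L  # bracket atom without H spec carries no implicit H
  list(num_atoms = 1L, atom_symbols = sym,
       edges = matrix(integer(0), ncol = 2L,
                      dimnames = list(NULL, c("from", "to"))),
       bond_orders = integer(0), degree = 0L,
       n_hydrogens = as.integer(n_h), implicit_valence = as.integer(n_h),
       aromatic = FALSE)
}

#' Featurize the atoms of a molecular graph
#'
#' Encodes the five per-atom descriptors (element, heavy degree, implicit
#' valence, attached hydrogens, aromaticity) into the fixed-width scheme of
#' [atom_feature_info()]. Elements outside the vocabulary map to the "other"
#' slot.
#'
#' @param graph A `molecular_graph` from [smiles_to_graph()].
#' @return A numeric matrix with one row per atom and
#'   `atom_feature_info()$width` columns.
#' @export
#' @examples
#' featurize_atoms(smiles_to_graph("C", featurize = FALSE))
featurize_atoms <- function(graph) {
  if (!inherits(graph, "molecular_graph"))
    stop("'graph' must be a molecular_graph", call. = FALSE)
  info <- atom_feature_info()
  n <- graph$num_atoms
  rows <- lapply(seq_len(n), function(i) {
    sym_idx <- match(graph$atom_symbols[i], info$elements,
                     nomatch = length(info$elements) + 1L)
    c(one_hot(sym_idx, info$widths[["symbol"]]),
      count_one_hot(graph$degree[i], info$count_cap),
      count_one_hot(graph$implicit_valence[i], info$count_cap),
      count_one_hot(graph$n_hydrogens[i], info$count_cap),
      as.numeric(graph$aromatic[i]))
  })
  m <- do.call(rbind, rows)
  rownames(m) <- paste0(graph$atom_symbols, "_", seq_len(n))
  m
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("Molecular graph: %s\n", x$smiles))
  cat(sprintf("  %d heavy atoms (%s), %d bonds, %d aromatic atoms\n",
              x$num_atoms,
              paste(unique(x$atom_symbols), collapse = ", "),
              nrow(x$edges), sum(x$aromatic)))
  invisible(x)
}

#' Read a drug table (id, smiles) from delimited text
#'
#' @param path Path to a CSV/TSV file with columns `drug_id` and `smiles`,
#'   or a file of bare SMILES strings one per line (ids are then assigned
#'   `drug1`, `drug2`, ...).
#' @return A data.frame with columns `drug_id` and `smiles`.
#' @export
read_drug_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("drug table not found: %s", path), call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  if (grepl("drug_id", first, fixed = TRUE)) {
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, comment.char = "")
    if (!all(c("drug_id", "smiles") %in% names(df)))
      stop(sprintf("drug table %s must have columns drug_id, smiles", path),
           call. = FALSE)
    df[, c("drug_id", "smiles")]
  } else {
    smi <- readLines(path)
    smi <- smi[nzchar(trimws(smi))]
    data.frame(drug_id = paste0("drug", seq_along(smi)), smiles = trimws(smi),
               stringsAsFactors = FALSE)
  }
}
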