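#' @importFrom rlang .data abort warn inform %||%
#' @importFrom tibble tibble as_tibble
NULL

# Supported-element vocabulary for the one-hot block; anything else maps to
# the trailing "other" slot.
.atomuq_elements <- c("C", "N", "O", "F", "P", "S", "Cl", "Br", "I")

.atomuq_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  P = 30.974, S = 32.06, Cl = 35.45, Br = 79.904, I = 126.904
)

# MOL2 charge/valence bookkeeping is delegated to OpenBabel; this reader only
# tokenizes the TRIPOS blocks it emits.
parse_mol2 <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  sec <- function(name) {
    i <- match(paste0("@<TRIPOS>", name), lines)
    if (is.na(i)) return(character(0))
    j <- i + 1L
    out <- character(0)
    while (j <= length(lines) && !startsWith(lines[j], "@<TRIPOS>")) {
      if (nzchar(trimws(lines[j]))) out <- c(out, lines[j])
      j <- j + 1L
    }
    out
  }
  atom_lines <- sec("ATOM")
  atoms <- if (length(atom_lines)) {
    f <- strsplit(trimws(atom_lines), "\\s+")
    tibble(
      idx = vapply(f, function(x) as.integer(x[1]), integer(1)),
      element = vapply(f, function(x) sub("\\..*$", "", x[6]), character(1)),
      sybyl = vapply(f, function(x) x[6], character(1))
    )
  } else {
    tibble(idx = integer(0), element = character(0), sybyl = character(0))
  }
  bond_lines <- sec("BOND")
  bonds <- if (length(bond_lines)) {
    f <- strsplit(trimws(bond_lines), "\\s+")
    tibble(
      a1 = vapply(f, function(x) as.integer(x[2]), integer(1)),
      a2 = vapply(f, function(x) as.integer(x[3]), integer(1)),
      type = vapply(f, function(x) x[4], character(1))
    )
  } else {
    tibble(a1 = integer(0), a2 = integer(0), type = character(0))
  }
  # formal charges arrive in UNITY_ATOM_ATTR as "<idx>\n charge <q>" pairs
  charges <- rep(0L, nrow(atoms))
  attr_lines <- sec("UNITY_ATOM_ATTR")
  if (length(attr_lines)) {
    i <- 1L
    while (i <= length(attr_lines)) {
      hdr <- strsplit(trimws(attr_lines[i]), "\\s+")[[1]]
      idx <- as.integer(hdr[1])
      n_attr <- as.integer(hdr[2])
      for (k in seq_len(n_attr)) {
        kv <- strsplit(trimws(attr_lines[i + k]), "\\s+")[[1]]
        if (identical(kv[1], "charge")) charges[idx] <- as.integer(kv[2])
      }
      i <- i + 1L + n_attr
    }
  }
  atoms$charge <- charges
  list(atoms = atoms, bonds = bonds)
}

smiles_to_mol2 <- function(smiles) {
  opts <- data.frame(names = "h", args = "", stringsAsFactors = FALSE)
  txt <- suppressWarnings(
    try(ChemmineOB::convertFormat("SMI", "MOL2", paste0(smiles, "\n"),
                                  options = opts), silent = TRUE)
  )
  if (inherits(txt, "try-error") || !is.character(txt) || !nzchar(txt)) {
    return(NULL)
  }
  txt
}

one_hot <- function(value, choices) {
  v <- as.numeric(choices == value)
  if (sum(v) == 0) c(rep(0, length(choices)), 1) else c(v, 0)
}

hybridization_of <- function(sybyl) {
  suffix <- sub("^[^.]*\\.?", "", sybyl)
  switch(suffix,
    "1" = "sp",
    "2" = "sp2",
    "co2" = "sp2",
    "ar" = "sp2",
    "pl3" = "sp2",
    "am" = "sp2",
    "3" = "sp3",
    "other"
  )
}

#' Featurize a SMILES string into a directed molecular graph
#'
#' Parses a SMILES string (through OpenBabel) into a heavy-atom molecular
#' graph with atom and bond feature vectors and the directed-edge topology
#' used by the message passing encoder. Hydrogens are implicit: they are
#' counted as an atom feature but contribute no graph nodes.
#'
#' Atom features: element one-hot over C/N/O/F/P/S/Cl/Br/I plus "other",
#' heavy-atom degree one-hot (0-5), formal charge one-hot (-2..+2, other),
#' bonded-hydrogen count one-hot (0-4), hybridization one-hot
#' (sp/sp2/sp3/other), aromaticity flag, and atomic mass scaled by 1/100.
#' Bond features: a "no-bond" slot (always 0 for real bonds), bond-type
#' one-hot (single/double/triple/aromatic-or-amide), conjugation flag, and
#' in-ring flag. Every bond contributes two directed edges; each directed
#' edge stores the index of its reverse.
#'
#' @param smiles A single SMILES string.
#' @return An object of class `mol_graph`: a list with `n_atoms`, `n_bonds`,
#'   `atom_features` (n_atoms x 35 matrix), `bond_features` (one row per
#'   directed edge), `edge_src`, `edge_dst`, `rev_edge` (integer vectors over
#'   directed edges), `element` (character vector in atom order), and
#'   `smiles`.
#' @examples
#' g <- featurize_molecule("CO")
#' g$n_atoms      # 2
#' g$rev_edge     # c(2, 1)
#' @export
featurize_molecule <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  txt <- smiles_to_mol2(smiles)
  if (is.null(txt)) {
    abort(sprintf("SMILES string could not be parsed: '%s'", smiles))
  }
  mol <- parse_mol2(txt)
  atoms <- mol$atoms
  bonds <- mol$bonds
  heavy <- atoms$element != "H"
  if (!any(heavy)) {
    abort(sprintf("SMILES '%s' contains no heavy atoms", smiles))
  }
  heavy_idx <- atoms$idx[heavy]
  remap <- rep(NA_integer_, max(atoms$idx))
  remap[heavy_idx] <- seq_along(heavy_idx)
  n <- length(heavy_idx)

  is_h <- !heavy
  h_count <- integer(n)
  heavy_bond <- bonds$a1 %in% heavy_idx & bonds$a2 %in% heavy_idx
  for (k in seq_len(nrow(bonds))) {
    a1 <- bonds$a1[k]; a2 <- bonds$a2[k]
    if (is_h[match(a1, atoms$idx)] && !is_h[match(a2, atoms$idx)]) {
      h_count[remap[a2]] <- h_count[remap[a2]] + 1L
    } else if (is_h[match(a2, atoms$idx)] && !is_h[match(a1, atoms$idx)]) {
      h_count[remap[a1]] <- h_count[remap[a1]] + 1L
    }
  }
  hb <- bonds[heavy_bond, , drop = FALSE]
  b1 <- remap[hb$a1]; b2 <- remap[hb$a2]
  n_bonds <- nrow(hb)

  degree <- tabulate(c(b1, b2), nbins = n)

  # a bond lies in a ring iff it is not a bridge of the heavy-atom graph
  in_ring <- rep(FALSE, n_bonds)
  if (n_bonds > 0) {
    g <- igraph::graph_from_edgelist(cbind(b1, b2), directed = FALSE)
    br <- igraph::bridges(g)
    in_ring <- !(seq_len(n_bonds) %in% as.integer(br))
  }

  el <- atoms$element[heavy]
  sybyl <- atoms$sybyl[heavy]
  charge <- atoms$charge[heavy]
  aromatic_atom <- grepl("\\.ar$", sybyl)
  hyb <- vapply(sybyl, hybridization_of, character(1))
  multiple <- grepl("\\.(1|2|ar|co2|am)$", sybyl)

  atom_features <- t(vapply(seq_len(n), function(i) {
    mass <- unname(.atomuq_masses[el[i]])
    c(
      one_hot(el[i], .atomuq_elements),
      one_hot(min(degree[i], 5L), 0:5),
      one_hot(max(min(charge[i], 2L), -2L), -2:2),
      one_hot(min(h_count[i], 4L), 0:4),
      one_hot(hyb[i], c("sp", "sp2", "sp3")),
      as.numeric(aromatic_atom[i]),
      if (is.na(mass)) 0 else mass / 100
    )
  }, numeric(35)))
  atom_features <- matrix(atom_features, nrow = n)

  bond_type_feature <- function(type) {
    # slot 1 is the "no-bond" indicator, kept 0 for every real bond
    c(0, switch(type,
      "1" = c(1, 0, 0, 0),
      "2" = c(0, 1, 0, 0),
      "3" = c(0, 0, 1, 0),
      "ar" = c(0, 0, 0, 1),
      "am" = c(0, 0, 0, 1),
      c(1, 0, 0, 0)
    ))
  }

  edge_src <- integer(2 * n_bonds)
  edge_dst <- integer(2 * n_bonds)
  rev_edge <- integer(2 * n_bonds)
  bond_features <- matrix(0, nrow = 2 * n_bonds, ncol = 7)
  for (k in seq_len(n_bonds)) {
    conj <- hb$type[k] %in% c("ar", "am") || (multiple[b1[k]] && multiple[b2[k]])
    bf <- c(bond_type_feature(hb$type[k]), as.numeric(conj), as.numeric(in_ring[k]))
    e1 <- 2L * k - 1L; e2 <- 2L * k
    edge_src[e1] <- b1[k]; edge_dst[e1] <- b2[k]
    edge_src[e2] <- b2[k]; edge_dst[e2] <- b1[k]
    rev_edge[e1] <- e2; rev_edge[e2] <- e1
    bond_features[e1, ] <- bf
    bond_features[e2, ] <- bf
  }

  structure(
    list(
      n_atoms = n,
      n_bonds = n_bonds,
      atom_features = atom_features,
      bond_features = bond_features,
      edge_src = edge_src,
      edge_dst = edge_dst,
      rev_edge = rev_edge,
      element = el,
      smiles = smiles
    ),
    class = "mol_graph"
  )
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf(
    "<mol_graph> %s: %d heavy atoms, %d bonds, %d directed edges\n",
    x$smiles, x$n_atoms, x$n_bonds, 2L * x$n_bonds
  ))
  invisible(x)
}

# Package-level featurization memo: SMILES -> mol_graph. Graphs are pure
# functions of the SMILES string, so the cache is safe to keep for the
# session (ensembles refeaturize the same molecules once per member
# otherwise).
.graph_cache <- new.env(parent = emptyenv())

# Featurize a vector of SMILES, memoizing repeats across calls. Returns a
# list of mol_graph (NULL where unparseable).
featurize_all <- function(smiles) {
  uniq <- unique(smiles)
  new <- uniq[!vapply(uniq, exists, logical(1), envir = .graph_cache)]
  for (s in new) {
    assign(s, tryCatch(featurize_molecule(s), error = function(e) NULL),
           envir = .graph_cache)
  }
  out <- mget(smiles, envir = .graph_cache)
  names(out) <- NULL
  out
}

#' Read a SMILES/property table from CSV
#'
#' Reads a CSV with one molecule per row, validates that each SMILES parses
#' to at least one heavy atom and that each target is finite, and returns a
#' tibble of the valid records. Unparseable rows are dropped with a message
#' reporting the count.
#'
#' @param path Path to a CSV file with a header row.
#' @param smiles_col,target_col Column names holding the SMILES string and
#'   the numeric property (defaults `"smiles"`, `"target"`).
#' @return A tibble with columns `id` (stable row identifier), `smiles`, `y`.
#' @export
read_molecule_table <- function(path, smiles_col = "smiles", target_col = "target") {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c(smiles_col, target_col) %in% names(df))) {
    abort(sprintf(
      "columns '%s' and '%s' must be present in %s",
      smiles_col, target_col, path
    ))
  }
  if (nrow(df) == 0) abort(sprintf("no rows in %s", path))
  out <- tibble(
    id = if ("id" %in% names(df)) as.character(df$id) else sprintf("mol_%05d", seq_len(nrow(df))),
    smiles = as.character(df[[smiles_col]]),
    y = as.numeric(df[[target_col]])
  )
  graphs <- featurize_all(out$smiles)
  ok <- !vapply(graphs, is.null, logical(1)) & is.finite(out$y)
  n_bad <- sum(!ok)
  if (n_bad > 0) {
    inform(sprintf("skipped %d record(s) with unparseable SMILES or non-finite targets", n_bad))
  }
  out <- out[ok, , drop = FALSE]
  if (nrow(out) == 0) abort("no valid records after parsing")
  out
}

#' Split molecules into train/validation/test sets
#'
#' Shuffles the records with a dedicated seeded generator and partitions them
#' 8:1:1: `floor(0.8 N)` train, `floor(0.1 N)` validation, remainder test.
#' The split seed is independent of any model seed.
#'
#' @param data A data frame with an `id` column (one row per record).
#' @param seed Integer seed controlling the shuffle.
#' @return The input tibble with an added `split` factor column
#'   (train/valid/test); the seed is attached as attribute `"split_seed"`.
#' @export
split_molecules <- function(data, seed) {
  n <- nrow(data)
  if (n < 3) abort("need at least 3 records to populate train/valid/test")
  perm <- withr::with_seed(as.integer(seed), sample.int(n))
  n_train <- floor(0.8 * n)
  n_valid <- floor(0.1 * n)
  split <- character(n)
  split[perm[seq_len(n_train)]] <- "train"
  split[perm[n_train + seq_len(n_valid)]] <- "valid"
  split[perm[(n_train + n_valid + 1):n]] <- "test"
  out <- as_tibble(data)
  out$split <- factor(split, levels = c("train", "valid", "test"))
  attr(out, "split_seed") <- as.integer(seed)
  out
}

#' Write or read a split manifest
#'
#' The manifest is a JSON file recording the record ids assigned to each
#' split and the seed that produced the assignment.
#'
#' @param data A tibble from [split_molecules()].
#' @param path Output JSON path.
#' @return `write_split_manifest()` returns `path` invisibly;
#'   `read_split_manifest()` returns a list with `train`, `valid`, `test`
#'   id vectors and `seed`.
#' @export
write_split_manifest <- function(data, path) {
  stopifnot("split" %in% names(data))
  manifest <- list(
    seed = attr(data, "split_seed"),
    train = data$id[data$split == "train"],
    valid = data$id[data$split == "valid"],
    test = data$id[data$split == "test"]
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_split_manifest
#' @export
read_split_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
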