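#' Create directed message passing encoder parameters
#'
#' Builds the weight set for the D-MPNN encoder: an input projection applied
#' to the concatenation of source-atom and bond features, a shared message
#' update transform, and an atom-aggregation transform that turns incoming
#' edge states plus raw atom features into atomic fingerprints. Weights are
#' Glorot-uniform initialized from `seed`; biases start at zero.
#'
#' @param atom_dim,bond_dim Widths of the atom and bond feature vectors
#'   (35 and 7 for [featurize_molecule()] graphs).
#' @param hidden_dim Fingerprint width `d`.
#' @param depth Number of message passing iterations `t` (default 2).
#' @param seed Integer seed for weight initialization.
#' @return An object of class `encoder_params`.
#' @export
encoder_params <- function(atom_dim, bond_dim, hidden_dim = 300, depth = 2, seed = 1) {
  stopifnot(depth >= 1, hidden_dim >= 1)
  withr::with_seed(as.integer(seed), {
    p <- list(
      W_i = glorot(atom_dim + bond_dim, hidden_dim, stats::runif),
      b_i = numeric(hidden_dim),
      W_h = glorot(hidden_dim, hidden_dim, stats::runif),
      b_h = numeric(hidden_dim),
      W_a = glorot(atom_dim + hidden_dim, hidden_dim, stats::runif),
      b_a = numeric(hidden_dim)
    )
    structure(
      c(p, list(atom_dim = atom_dim, bond_dim = bond_dim,
                hidden_dim = hidden_dim, depth = depth)),
      class = "encoder_params"
    )
  })
}

#' Initialize directed edge states
#'
#' Projects, for every directed edge u->v, the concatenation of the source
#' atom's features and the bond's features through the input layer and ReLU,
#' yielding the initial edge hidden states.
#'
#' @param graph A [featurize_molecule()] graph.
#' @param params An [encoder_params()] object.
#' @return A matrix with one row per directed edge (`0` rows for bond-free
#'   molecules) and `hidden_dim` columns.
#' @export
init_directed_messages <- function(graph, params) {
  check_encoder_dims(graph, params)
  d <- params$hidden_dim
  if (2L * graph$n_bonds == 0L) return(matrix(0, 0, d))
  Z <- cbind(graph$atom_features[graph$edge_src, , drop = FALSE],
             graph$bond_features)
  relu(sweep(Z %*% params$W_i, 2, params$b_i, "+"))
}

check_encoder_dims <- function(graph, params) {
  if (ncol(graph$atom_features) != params$atom_dim ||
      ncol(graph$bond_features) != params$bond_dim) {
    rlang::abort(sprintf(
      "encoder expects atom/bond feature widths %d/%d, graph has %d/%d",
      params$atom_dim, params$bond_dim,
      ncol(graph$atom_features), ncol(graph$bond_features)
    ))
  }
  invisible(TRUE)
}

#' One directed message passing update
#'
#' For each directed edge u->v, sums the states of edges incoming at u
#' excluding the reverse edge v->u, applies the message transform, adds the
#' skip connection from the initial edge states, and applies ReLU.
#'
#' @param edge_states Current edge-state matrix.
#' @param graph A [featurize_molecule()] graph.
#' @param params An [encoder_params()] object.
#' @param h0 Initial edge states from [init_directed_messages()] (the skip
#'   connection); defaults to `edge_states`, which is correct only for the
#'   first step.
#' @return Updated edge-state matrix.
#' @export
message_passing_step <- function(edge_states, graph, params, h0 = edge_states) {
  if (nrow(edge_states) == 0) return(edge_states)
  S <- atom_sum(edge_states, graph$edge_dst, graph$n_atoms)
  M <- S[graph$edge_src, , drop = FALSE] - edge_states[graph$rev_edge, , drop = FALSE]
  relu(h0 + sweep(M %*% params$W_h, 2, params$b_h, "+"))
}

#' Encode atoms into learned fingerprints
#'
#' Runs initialization plus `depth` message passing steps, then aggregates
#' each atom's incoming edge states together with its raw features through
#' the atom transform, producing the learned atomic fingerprint matrix
#' (one row per atom).
#'
#' @inheritParams init_directed_messages
#' @return An `n_atoms x hidden_dim` fingerprint matrix.
#' @examples
#' g <- featurize_molecule("c1ccccc1")
#' ep <- encoder_params(35, 7, hidden_dim = 16, seed = 1)
#' fp <- encode_atoms(g, ep)
#' max(dist(fp))  # ~0: all benzene carbons are equivalent
#' @export
encode_atoms <- function(graph, params) {
  h0 <- init_directed_messages(graph, params)
  h <- h0
  for (k in seq_len(params$depth)) {
    h <- message_passing_step(h, graph, params, h0 = h0)
  }
  A_in <- atom_sum(h, graph$edge_dst, graph$n_atoms)
  Q <- cbind(graph$atom_features, A_in)
  relu(sweep(Q %*% params$W_a, 2, params$b_a, "+"))
}

# --- batched internals -----------------------------------------------------

# Concatenate graphs into one block-diagonal graph for vectorized training.
batch_graphs <- function(graphs) {
  n_atoms <- vapply(graphs, function(g) g$n_atoms, integer(1))
  n_edges <- vapply(graphs, function(g) 2L * g$n_bonds, integer(1))
  atom_off <- cumsum(c(0L, n_atoms[-length(n_atoms)]))
  edge_off <- cumsum(c(0L, n_edges[-length(n_edges)]))
  list(
    atom_features = do.call(rbind, lapply(graphs, function(g) g$atom_features)),
    bond_features = do.call(rbind, lapply(graphs, function(g) g$bond_features)),
    edge_src = unlist(lapply(seq_along(graphs), function(i) graphs[[i]]$edge_src + atom_off[i])),
    edge_dst = unlist(lapply(seq_along(graphs), function(i) graphs[[i]]$edge_dst + atom_off[i])),
    rev_edge = unlist(lapply(seq_along(graphs), function(i) graphs[[i]]$rev_edge + edge_off[i])),
    mol_of_atom = rep(seq_along(graphs), n_atoms),
    n_atoms = n_atoms,
    n_mols = length(graphs),
    total_atoms = sum(n_atoms),
    element = unlist(lapply(graphs, function(g) g$element))
  )
}

# Forward pass through the encoder on a batched graph, keeping the
# intermediates needed for backpropagation.
encoder_forward <- function(bg, ep, keep_cache = TRUE) {
  d <- ep$hidden_dim
  ne <- length(bg$edge_src)
  if (ne > 0) {
    Z <- cbind(bg$atom_features[bg$edge_src, , drop = FALSE], bg$bond_features)
    P0 <- sweep(Z %*% ep$W_i, 2, ep$b_i, "+")
    H0 <- relu(P0)
  } else {
    Z <- matrix(0, 0, ep$atom_dim + ep$bond_dim)
    P0 <- H0 <- matrix(0, 0, d)
  }
  H <- H0
  Ms <- vector("list", ep$depth)
  Ps <- vector("list", ep$depth)
  Hs <- vector("list", ep$depth + 1)
  Hs[[1]] <- H0
  for (k in seq_len(ep$depth)) {
    if (ne > 0) {
      S <- atom_sum(H, bg$edge_dst, bg$total_atoms)
      M <- S[bg$edge_src, , drop = FALSE] - H[bg$rev_edge, , drop = FALSE]
      P <- H0 + sweep(M %*% ep$W_h, 2, ep$b_h, "+")
      H <- relu(P)
    } else {
      M <- P <- matrix(0, 0, d)
    }
    Ms[[k]] <- M; Ps[[k]] <- P; Hs[[k + 1]] <- H
  }
  A_in <- atom_sum(H, bg$edge_dst, bg$total_atoms)
  Q <- cbind(bg$atom_features, A_in)
  Pa <- sweep(Q %*% ep$W_a, 2, ep$b_a, "+")
  Fp <- relu(Pa)
  out <- list(F = Fp)
  if (keep_cache) {
    out$cache <- list(Z = Z, P0 = P0, Ms = Ms, Ps = Ps, Hs = Hs, Q = Q, Pa = Pa)
  }
  out
}

# Backpropagate d(loss)/d(F) through the encoder; returns gradients for the
# encoder parameter arrays.
encoder_backward <- function(gF, bg, ep, cache) {
  d <- ep$hidden_dim
  ne <- length(bg$edge_src)
  gPa <- gF * (cache$Pa > 0)
  g <- list(
    W_a = crossprod(cache$Q, gPa),
    b_a = colSums(gPa),
    W_h = matrix(0, d, d),
    b_h = numeric(d),
    W_i = matrix(0, ep$atom_dim + ep$bond_dim, d),
    b_i = numeric(d)
  )
  if (ne == 0) return(g)
  gAin <- gPa %*% t(ep$W_a[(ep$atom_dim + 1):(ep$atom_dim + d), , drop = FALSE])
  gH <- gAin[bg$edge_dst, , drop = FALSE]   # final edge states
  gH0 <- matrix(0, ne, d)
  for (k in rev(seq_len(ep$depth))) {
    gP <- gH * (cache$Ps[[k]] > 0)
    gH0 <- gH0 + gP
    g$W_h <- g$W_h + crossprod(cache$Ms[[k]], gP)
    g$b_h <- g$b_h + colSums(gP)
    gM <- gP %*% t(ep$W_h)
    Tm <- atom_sum(gM, bg$edge_src, bg$total_atoms)
    gH <- Tm[bg$edge_dst, , drop = FALSE] - gM[bg$rev_edge, , drop = FALSE]
  }
  gH0 <- gH0 + gH
  gP0 <- gH0 * (cache$P0 > 0)
  g$W_i <- crossprod(cache$Z, gP0)
  g$b_i <- colSums(gP0)
  g
}
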