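#' Specification for the synthetic additive-property generator
#'
#' The generator emulates the heteroscedastic structure the atom-based model
#' assumes: each molecule is a random valence-respecting graph over a small
#' element vocabulary and its property is an exact sum of per-element atomic
#' contributions plus independent per-atom Gaussian noise whose scale is
#' keyed to the element. The additive ground truth makes atomic attribution
#' directly checkable.
#'
#' @param n_molecules Number of molecules to generate.
#' @param contributions Named numeric vector of per-element additive
#'   contributions (property units).
#' @param noise_scales Named numeric vector of per-element noise standard
#'   deviations (>= 0); one independent draw per atom.
#' @param size_range Integer range of heavy-atom counts.
#' @param ring_prob Probability that a molecule receives one ring-closure
#'   bond (when two eligible atoms exist).
#' @param element_weights Sampling weights over the vocabulary.
#' @param seed Integer seed; generation is fully reproducible.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_molecules = 500,
                           contributions = c(C = -1.2, N = 0.8, O = 2.3, F = -0.5),
                           noise_scales = c(C = 0.1, N = 0.1, O = 0.1, F = 0.1),
                           size_range = c(3, 12),
                           ring_prob = 0.15,
                           element_weights = c(C = 0.6, N = 0.15, O = 0.15, F = 0.1),
                           seed = 1) {
  if (length(contributions) == 0) rlang::abort("element vocabulary must be non-empty")
  stopifnot(all(is.finite(contributions)), all(noise_scales >= 0))
  if (!setequal(names(contributions), names(noise_scales)) ||
      !setequal(names(contributions), names(element_weights))) {
    rlang::abort("contributions, noise_scales and element_weights must share element names")
  }
  structure(list(
    n_molecules = n_molecules, contributions = contributions,
    noise_scales = noise_scales[names(contributions)],
    size_range = size_range, ring_prob = ring_prob,
    element_weights = element_weights[names(contributions)],
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

.valence <- c(C = 4, N = 3, O = 2, F = 1, P = 3, S = 2, Cl = 1, Br = 1, I = 1)

# Write a SMILES string for a single-bonded graph given as a tree (parent
# pointers) plus optional extra ring bonds; ring closures get digits.
graph_to_smiles <- function(elements, parent, ring_bonds) {
  n <- length(elements)
  children <- vector("list", n)
  for (v in seq_len(n)[-1]) {
    children[[parent[v]]] <- c(children[[parent[v]]], v)
  }
  ring_digits <- vector("list", n)
  if (length(ring_bonds)) {
    for (k in seq_along(ring_bonds)) {
      a <- ring_bonds[[k]][1]; b <- ring_bonds[[k]][2]
      ring_digits[[a]] <- c(ring_digits[[a]], k)
      ring_digits[[b]] <- c(ring_digits[[b]], k)
    }
  }
  emit <- function(v) {
    tok <- paste0(elements[v], paste(ring_digits[[v]], collapse = ""))
    kids <- children[[v]]
    if (length(kids) == 0) return(tok)
    inner <- vapply(kids, emit, character(1))
    if (length(inner) > 1) {
      tok <- paste0(tok, paste0("(", inner[-length(inner)], ")", collapse = ""))
    }
    paste0(tok, inner[length(inner)])
  }
  emit(1L)
}

#' Generate a synthetic SMILES dataset with additive atomic ground truth
#'
#' Assembles random valence-respecting molecular graphs (trees with an
#' occasional ring closure) over the spec's element vocabulary, writes them
#' as SMILES, and labels each molecule with
#' `y = sum(contribution[element]) + sum(noise_scale[element] * eps)` with
#' independent standard-normal `eps` per atom. The noise-free contribution
#' sum and the exact per-molecule noise variance are recorded alongside.
#'
#' @param spec A [synthetic_spec()].
#' @return A tibble with `id`, `smiles`, `y`, `true_sum` (noise-free value),
#'   `true_noise_var` (sum of squared per-atom noise scales), `n_atoms`.
#' @export
generate_molecules <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  elements_vocab <- names(spec$contributions)
  withr::with_seed(spec$seed, {
    rows <- lapply(seq_len(spec$n_molecules), function(i) {
      size <- sample(spec$size_range[1]:spec$size_range[2], 1)
      el <- character(size)
      parent <- integer(size)
      # first atom must be able to bond if the molecule grows
      w1 <- spec$element_weights
      if (size > 1) w1[.valence[elements_vocab] < 2] <- 0
      el[1] <- sample(elements_vocab, 1, prob = w1)
      free <- .valence[el[1]]
      for (v in seq_len(size)[-1]) {
        cand <- which(free > 0)
        if (length(cand) == 0) { el <- el[seq_len(v - 1)]; parent <- parent[seq_len(v - 1)]; break }
        p <- if (length(cand) == 1) cand else sample(cand, 1)
        el[v] <- sample(elements_vocab, 1, prob = spec$element_weights)
        parent[v] <- p
        free[p] <- free[p] - 1L
        free <- c(free, .valence[el[v]] - 1L)
      }
      n <- length(el)
      ring_bonds <- list()
      if (n >= 3 && stats::runif(1) < spec$ring_prob) {
        adj <- cbind(seq_len(n)[-1], parent[-1])
        open <- which(free > 0)
        pairs <- if (length(open) >= 2) utils::combn(open, 2, simplify = FALSE) else list()
        pairs <- Filter(function(p) {
          !any(adj[, 1] == p[2] & adj[, 2] == p[1]) &&
            !any(adj[, 1] == p[1] & adj[, 2] == p[2])
        }, pairs)
        if (length(pairs) > 0) {
          pick <- pairs[[if (length(pairs) == 1) 1 else sample(length(pairs), 1)]]
          ring_bonds <- list(pick)
        }
      }
      smiles <- graph_to_smiles(el, parent, ring_bonds)
      contrib <- sum(spec$contributions[el])
      scales <- spec$noise_scales[el]
      noise <- sum(scales * stats::rnorm(n))
      tibble::tibble(
        smiles = smiles, y = contrib + noise, true_sum = contrib,
        true_noise_var = sum(scales^2), n_atoms = n
      )
    })
    out <- dplyr::bind_rows(rows)
    tibble::add_column(out, id = sprintf("syn_%05d", seq_len(nrow(out))), .before = 1)
  })
}

#' Count atoms of an element in each SMILES
#'
#' Counts heavy atoms of `element` through featurization (not by string
#' matching, which would confuse e.g. N and Na).
#'
#' @param smiles Character vector of SMILES.
#' @param element Element symbol.
#' @return Integer vector of counts.
#' @export
count_element <- function(smiles, element) {
  graphs <- featurize_all(smiles)
  vapply(graphs, function(g) {
    if (is.null(g)) NA_integer_ else sum(g$element == element)
  }, integer(1))
}

#' Inject element-keyed label noise
#'
#' For each record, adds the sum of `r` independent standard-normal draws to
#' the property, where `r` is the number of heavy atoms of `element` in the
#' molecule. Records without the element are bit-unchanged (the empty sum).
#' Emulates heterogeneous data quality concentrated on one element.
#'
#' @param data Tibble with `smiles` and `y`.
#' @param element Element symbol carrying the noise (default `"N"`).
#' @param seed Dedicated seed for the noise stream, independent of model and
#'   split seeds.
#' @return `data` with `y` replaced by the noisy value and an added
#'   `n_noise_atoms` column holding `r`.
#' @export
inject_label_noise <- function(data, element = "N", seed = 1) {
  r <- count_element(data$smiles, element)
  if (any(is.na(r))) rlang::abort("all records must be featurizable")
  noise <- withr::with_seed(as.integer(seed), {
    vapply(r, function(k) if (k > 0) sum(stats::rnorm(k)) else 0, numeric(1))
  })
  out <- data
  out$y <- data$y + noise
  out$n_noise_atoms <- r
  out
}

#' Remove molecules containing an element
#'
#' Keeps only molecules with zero heavy atoms of `element`, reporting how
#' many were removed. Used to train element-ignorant models that have never
#' seen the element.
#'
#' @inheritParams inject_label_noise
#' @return The filtered tibble.
#' @export
filter_out_element <- function(data, element) {
  r <- count_element(data$smiles, element)
  if (any(is.na(r))) rlang::abort("all records must be featurizable")
  keep <- r == 0
  if (!any(keep)) {
    rlang::abort(sprintf("removing '%s' molecules would empty the dataset", element))
  }
  rlang::inform(sprintf("removed %d molecule(s) containing %s", sum(!keep), element))
  data[keep, , drop = FALSE]
}

#' Summarize predicted uncertainty by element count
#'
#' Groups test molecules by the number of heavy atoms of `element`
#' (0, 1, 2, 3+) and reports per-group sizes and mean/median aleatoric and
#' epistemic variances. Empty groups are simply absent.
#'
#' @param preds Tibble from [ensemble_predict()].
#' @param element Element symbol to count.
#' @return A tibble with one row per populated group.
#' @export
group_uncertainty_by_element_count <- function(preds, element) {
  r <- count_element(preds$smiles, element)
  grp <- ifelse(r >= 3, "3+", as.character(r))
  preds |>
    dplyr::mutate(group = factor(grp, levels = c("0", "1", "2", "3+"))) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_sigma2_ale = mean(.data$sigma2_ale),
      median_sigma2_ale = stats::median(.data$sigma2_ale),
      mean_sigma2_epi = mean(.data$sigma2_epi),
      median_sigma2_epi = stats::median(.data$sigma2_epi),
      .groups = "drop"
    )
}
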