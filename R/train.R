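#' Training configuration for a single uncertainty model
#'
#' @param mode `"atom"` (per-atom readout with covariance aggregation) or
#'   `"molecule"` (sum-pooled baseline readout).
#' @param hidden_dim Fingerprint width of the encoder.
#' @param trunk_dim Width of the shared readout trunk (defaults to
#'   `hidden_dim`).
#' @param depth Message passing iterations (default 2).
#' @param max_epochs,patience Optimization budget and early-stopping
#'   patience: training halts once the validation heteroscedastic loss has
#'   failed to improve for `patience` epochs (default 15).
#' @param batch_size,learning_rate Adam minibatch size and step size.
#' @param warmup_epochs For the first `warmup_epochs` epochs the predictive
#'   variance is held at 1 (an MSE-equivalent loss) to stabilize the mean
#'   before the variance path is enabled; set 0 to disable.
#' @param grad_clip Global gradient-norm clip.
#' @param seed Seed governing weight initialization and batch shuffling
#'   (the data split seed is separate; see [split_molecules()]).
#' @return A list of class `train_config`.
#' @export
train_config <- function(mode = c("atom", "molecule"), hidden_dim = 300,
                         trunk_dim = NULL, depth = 2, max_epochs = 150,
                         patience = 15, batch_size = 50, learning_rate = 1e-3,
                         warmup_epochs = 5, grad_clip = 10, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(patience >= 1, batch_size >= 1, learning_rate > 0, max_epochs >= 1)
  structure(list(
    mode = mode, hidden_dim = hidden_dim,
    trunk_dim = trunk_dim %||% hidden_dim, depth = depth,
    max_epochs = max_epochs, patience = patience, batch_size = batch_size,
    learning_rate = learning_rate, warmup_epochs = warmup_epochs,
    grad_clip = grad_clip, seed = as.integer(seed)
  ), class = "train_config")
}

as_encoder_view <- function(par, meta) {
  structure(c(par[c("W_i", "b_i", "W_h", "b_h", "W_a", "b_a")],
              meta[c("atom_dim", "bond_dim", "hidden_dim", "depth")]),
            class = "encoder_params")
}

as_head_view <- function(par, meta) {
  structure(c(par[c("W_t", "b_t", "w_mu", "b_mu", "w_vl", "b_vl", "log_scale")],
              meta[c("hidden_dim", "trunk_dim", "mode")]),
            class = "head_params")
}

init_model_params <- function(meta, seed) {
  ep <- encoder_params(meta$atom_dim, meta$bond_dim, meta$hidden_dim,
                       meta$depth, seed = seed)
  hp <- head_params(meta$hidden_dim, meta$trunk_dim, mode = meta$mode,
                    seed = seed + 500000L)
  c(ep[c("W_i", "b_i", "W_h", "b_h", "W_a", "b_a")],
    hp[c("W_t", "b_t", "w_mu", "b_mu", "w_vl", "b_vl", "log_scale")])
}

# Full forward pass on a batched graph in standardized target space.
# Returns per-molecule means and variances; in atom mode also the per-atom
# means/sigmas, the correlation products needed for gradients, and (optionally)
# per-molecule correlation matrices.
model_forward <- function(bg, par, meta, keep_cache = FALSE, keep_correlation = FALSE) {
  ep <- as_encoder_view(par, meta)
  hp <- as_head_view(par, meta)
  enc <- encoder_forward(bg, ep, keep_cache = keep_cache)
  rows <- split(seq_len(bg$total_atoms), bg$mol_of_atom)
  if (meta$mode == "atom") {
    hf <- heads_forward(enc$F, hp, keep_cache = keep_cache)
    sigma <- exp(par$log_scale) * (softplus(hf$raw) + .sigma_floor)
    mu_m <- unname(drop(rowsum(hf$mu, bg$mol_of_atom)))
    v_raw <- numeric(bg$n_mols)
    Rs <- numeric(bg$total_atoms)
    Rlist <- if (keep_correlation) vector("list", bg$n_mols)
    for (m in seq_len(bg$n_mols)) {
      r <- rows[[m]]
      R <- pairwise_correlation(enc$F[r, , drop = FALSE])
      rs <- drop(R %*% sigma[r])
      Rs[r] <- rs
      v_raw[m] <- sum(sigma[r] * rs)
      if (keep_correlation) Rlist[[m]] <- R
    }
    v <- pmax(v_raw, .var_floor)
    out <- list(mu_m = mu_m, v = v, v_raw = v_raw, mu_atoms = hf$mu,
                sigma_atoms = sigma, raw = hf$raw, rows = rows, Rs = Rs,
                correlations = if (keep_correlation) Rlist)
  } else {
    Fm <- rowsum(enc$F, bg$mol_of_atom)
    hf <- heads_forward(Fm, hp, keep_cache = keep_cache)
    v_raw <- exp(2 * par$log_scale) * (softplus(hf$raw) + .sigma_floor)
    v <- pmax(v_raw, .var_floor)
    out <- list(mu_m = hf$mu, v = v, v_raw = v_raw, raw = hf$raw, rows = rows)
  }
  if (keep_cache) {
    out$enc_cache <- enc$cache
    out$head_cache <- hf$cache
  }
  out
}

# Loss and parameter gradients for one batch (standardized targets).
# warm = TRUE fixes the variance at 1 and trains only the mean path.
# The correlation matrix is treated as a constant of the forward pass
# (stop-gradient); gradients flow through atomic means and sigmas.
model_loss_grads <- function(bg, par, meta, y_std, warm = FALSE) {
  fw <- model_forward(bg, par, meta, keep_cache = TRUE)
  B <- bg$n_mols
  v_loss <- if (warm) rep(1, B) else fw$v
  nll <- heteroscedastic_nll(fw$mu_m, v_loss, y_std)
  loss <- mean(nll)
  g_mu_m <- (fw$mu_m - y_std) / v_loss / B
  if (warm) {
    g_v <- numeric(B)
  } else {
    g_v <- (1 / (2 * fw$v) - (y_std - fw$mu_m)^2 / (2 * fw$v^2)) / B
    g_v[fw$v_raw < .var_floor] <- 0
  }
  hp <- as_head_view(par, meta)
  ep <- as_encoder_view(par, meta)
  if (meta$mode == "atom") {
    g_mu_atom <- g_mu_m[bg$mol_of_atom]
    g_sigma <- 2 * g_v[bg$mol_of_atom] * fw$Rs
    g_raw <- g_sigma * exp(par$log_scale) * sigmoid(fw$raw)
    g_ls <- sum(g_sigma * fw$sigma_atoms)
    hb <- heads_backward(g_mu_atom, g_raw, hp, fw$head_cache)
    gF <- hb$gF
  } else {
    g_raw <- g_v * exp(2 * par$log_scale) * sigmoid(fw$raw)
    g_ls <- sum(2 * g_v * fw$v_raw)
    hb <- heads_backward(g_mu_m, g_raw, hp, fw$head_cache)
    gF <- hb$gF[bg$mol_of_atom, , drop = FALSE]
  }
  eb <- encoder_backward(gF, bg, ep, fw$enc_cache)
  grads <- c(eb, hb$grads, list(log_scale = g_ls))
  if (warm) grads <- grads[setdiff(names(grads), vl_param_names())]
  list(loss = loss, grads = grads)
}

# Mean heteroscedastic NLL of a model over a batched graph (standardized y).
model_valid_nll <- function(bg, par, meta, y_std) {
  fw <- model_forward(bg, par, meta)
  mean(heteroscedastic_nll(fw$mu_m, fw$v, y_std))
}

#' Train a single heteroscedastic uncertainty model
#'
#' Minimizes the mean per-molecule heteroscedastic negative log-likelihood
#' with Adam on standardized targets, tracking the validation loss each
#' epoch and returning the parameters of the best validation epoch (early
#' stopping with the configured patience).
#'
#' @param train_data,valid_data Tibbles with `id`, `smiles`, `y` columns
#'   (e.g. rows of a [split_molecules()] result).
#' @param config A [train_config()].
#' @return An object of class `atomuq_model` with elements `par` (weights),
#'   `meta`, `norm` (target mean/sd), `config`, `history` (per-epoch tibble),
#'   `best_epoch`, and `valid_nll`.
#' @export
train_uncertainty_model <- function(train_data, valid_data, config = train_config()) {
  stopifnot(inherits(config, "train_config"))
  if (nrow(train_data) == 0 || nrow(valid_data) == 0) {
    rlang::abort("train and validation splits must be non-empty")
  }
  g_train <- featurize_all(train_data$smiles)
  g_valid <- featurize_all(valid_data$smiles)
  if (any(vapply(g_train, is.null, logical(1))) ||
      any(vapply(g_valid, is.null, logical(1)))) {
    rlang::abort("all training/validation SMILES must be featurizable")
  }
  meta <- list(
    atom_dim = ncol(g_train[[1]]$atom_features),
    bond_dim = ncol(g_train[[1]]$bond_features),
    hidden_dim = config$hidden_dim, trunk_dim = config$trunk_dim,
    depth = config$depth, mode = config$mode
  )
  mu_y <- mean(train_data$y)
  sd_y <- stats::sd(train_data$y)
  if (!is.finite(sd_y) || sd_y == 0) sd_y <- 1
  y_tr <- (train_data$y - mu_y) / sd_y
  y_va <- (valid_data$y - mu_y) / sd_y

  par <- init_model_params(meta, config$seed)
  opt <- adam_init(par, lr = config$learning_rate)
  bg_valid <- batch_graphs(g_valid)

  n <- nrow(train_data)
  best <- list(nll = Inf, par = par, epoch = 0L)
  history <- vector("list", config$max_epochs)
  stale <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    warm <- epoch <= config$warmup_epochs
    perm <- withr::with_seed(config$seed + 7919L * epoch, sample.int(n))
    batches <- split(perm, ceiling(seq_along(perm) / config$batch_size))
    ep_loss <- 0
    for (b in batches) {
      bg <- batch_graphs(g_train[b])
      lg <- model_loss_grads(bg, par, meta, y_tr[b], warm = warm)
      if (!is.finite(lg$loss)) {
        rlang::abort(sprintf("training loss became non-finite at epoch %d", epoch))
      }
      upd <- adam_step(par, lg$grads, opt, clip = config$grad_clip)
      par <- upd$params; opt <- upd$state
      ep_loss <- ep_loss + lg$loss * length(b)
    }
    v_nll <- model_valid_nll(bg_valid, par, meta, y_va)
    history[[epoch]] <- tibble::tibble(
      epoch = epoch, train_loss = ep_loss / n, valid_nll = v_nll, warmup = warm
    )
    if (v_nll < best$nll) {
      best <- list(nll = v_nll, par = par, epoch = epoch)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale > config$patience) break
    }
  }
  structure(list(
    par = best$par, meta = meta,
    norm = list(mean = mu_y, sd = sd_y),
    config = config,
    history = dplyr::bind_rows(history),
    best_epoch = best$epoch,
    valid_nll = best$nll
  ), class = "atomuq_model")
}

#' @export
print.atomuq_model <- function(x, ...) {
  cat(sprintf(
    "<atomuq_model> %s-based, d=%d, depth=%d; best epoch %d (valid NLL %.4f)\n",
    x$meta$mode, x$meta$hidden_dim, x$meta$depth, x$best_epoch, x$valid_nll
  ))
  invisible(x)
}

# Internal: predict on pre-featurized graphs; returns per-molecule mu/v in
# original units plus (atom mode) per-atom means and sigmas.
predict_on_graphs <- function(model, graphs) {
  bg <- batch_graphs(graphs)
  fw <- model_forward(bg, model$par, model$meta)
  s <- model$norm$sd; m0 <- model$norm$mean
  out <- list(
    mu = s * fw$mu_m + m0,
    sigma2 = s^2 * fw$v,
    n_atoms = bg$n_atoms,
    element = bg$element,
    mol_of_atom = bg$mol_of_atom
  )
  if (model$meta$mode == "atom") {
    n_per <- bg$n_atoms[bg$mol_of_atom]
    out$mu_atoms <- s * fw$mu_atoms + m0 / n_per
    out$sigma_atoms <- s * fw$sigma_atoms
  }
  out
}

#' Predict molecular property distributions
#'
#' Deterministic forward pass producing, per molecule, the predictive mean
#' and variance in original property units; in atom mode the per-atom means
#' and standard deviations are returned as a nested list-column (`atoms`).
#' The per-atom means sum exactly to the molecular mean.
#'
#' @param object A trained [train_uncertainty_model()] model.
#' @param newdata Tibble with `id` and `smiles` columns.
#' @param ... Unused.
#' @return A tibble with `id`, `smiles`, `mu`, `sigma2` and (atom mode) an
#'   `atoms` list-column of per-atom tibbles
#'   (`atom_index`, `element`, `mu_atom`, `sigma_atom`).
#' @export
predict.atomuq_model <- function(object, newdata, ...) {
  graphs <- featurize_all(newdata$smiles)
  bad <- vapply(graphs, is.null, logical(1))
  if (any(bad)) {
    rlang::warn(sprintf(
      "dropping %d unfeaturizable record(s): %s", sum(bad),
      paste(utils::head(newdata$id[bad], 5), collapse = ", ")
    ))
    newdata <- newdata[!bad, , drop = FALSE]
    graphs <- graphs[!bad]
  }
  if (length(graphs) == 0) rlang::abort("no featurizable records to predict on")
  pr <- predict_on_graphs(object, graphs)
  res <- tibble::tibble(id = newdata$id, smiles = newdata$smiles,
                        mu = pr$mu, sigma2 = pr$sigma2)
  if (object$meta$mode == "atom") {
    atoms_all <- tibble::tibble(
      mol = pr$mol_of_atom,
      element = pr$element,
      mu_atom = pr$mu_atoms,
      sigma_atom = pr$sigma_atoms
    )
    res$atoms <- lapply(seq_len(nrow(res)), function(m) {
      a <- atoms_all[atoms_all$mol == m, c("element", "mu_atom", "sigma_atom")]
      a <- tibble::add_column(a, atom_index = seq_len(nrow(a)) - 1L, .before = 1)
      a
    })
  }
  res
}

#' Save or load a model checkpoint
#'
#' The checkpoint is a single serialized file plus a JSON sidecar
#' (`<path>.json`) holding the configuration and the training history. A
#' loaded checkpoint reproduces its recorded validation loss exactly.
#'
#' @param model An `atomuq_model`.
#' @param path Destination file path.
#' @return `write_checkpoint()` returns `path` invisibly; `read_checkpoint()`
#'   returns the model.
#' @export
write_checkpoint <- function(model, path) {
  saveRDS(model, path)
  sidecar <- list(
    mode = model$meta$mode,
    config = unclass(model$config),
    norm = model$norm,
    best_epoch = model$best_epoch,
    valid_nll = model$valid_nll,
    history = model$history
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  readRDS(path)
}
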