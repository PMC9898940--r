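#' Train a Deep Ensemble of uncertainty models
#'
#' Trains `M` networks that differ only in their initialization and batch
#' shuffling seeds (`config$seed + 0 .. M-1`); data and splits are shared.
#'
#' @param train_data,valid_data Tibbles with `id`, `smiles`, `y`.
#' @param M Number of ensemble members (the reference configuration uses 30;
#'   scaled experiments use 3-5).
#' @param config Base [train_config()]; member `m` uses `config$seed + m - 1`.
#' @return An object of class `atomuq_ensemble`.
#' @export
train_ensemble <- function(train_data, valid_data, M, config = train_config()) {
  if (M < 1) rlang::abort("M must be >= 1")
  members <- lapply(seq_len(M), function(m) {
    cfg <- config
    cfg$seed <- config$seed + m - 1L
    train_uncertainty_model(train_data, valid_data, cfg)
  })
  structure(list(
    members = members, M = as.integer(M), mode = config$mode,
    base_seed = config$seed, calibrated = FALSE, calibration_history = NULL
  ), class = "atomuq_ensemble")
}

#' @export
print.atomuq_ensemble <- function(x, ...) {
  cat(sprintf("<atomuq_ensemble> %d %s-based members%s\n", x$M, x$mode,
              if (x$calibrated) " (post-hoc calibrated)" else ""))
  invisible(x)
}

#' Combine member Gaussian moments into ensemble moments
#'
#' Given per-record member means and variances, returns the ensemble mean
#' (average of member means), the aleatoric variance (average of member
#' variances) and the epistemic variance (population variance of the member
#' means, divisor `M`). The total ensemble variance satisfies the identity
#' `mean(sigma2 + mu^2) - mu_ens^2 = sigma2_ale + sigma2_epi`.
#'
#' @param mu_mat,v_mat Numeric matrices (`n_records x M`) of member means
#'   and variances.
#' @return A list with `mu_ens`, `sigma2_ale`, `sigma2_epi`.
#' @export
ensemble_moments <- function(mu_mat, v_mat) {
  mu_mat <- as.matrix(mu_mat)
  v_mat <- as.matrix(v_mat)
  stopifnot(identical(dim(mu_mat), dim(v_mat)), ncol(mu_mat) >= 1)
  mu_ens <- rowMeans(mu_mat)
  list(
    mu_ens = mu_ens,
    sigma2_ale = rowMeans(v_mat),
    sigma2_epi = rowMeans((mu_mat - mu_ens)^2)
  )
}

#' Ensemble prediction with aleatoric/epistemic decomposition
#'
#' Combines the `M` member Gaussians into the ensemble mean (average of the
#' member means), the aleatoric variance (average of the member variances)
#' and the epistemic variance (population variance of the member means,
#' divisor `M`). In atom mode the same decomposition is applied per atom to
#' the member atomic means and variances.
#'
#' @param ensemble An [train_ensemble()] object (or a list of models sharing
#'   one mode).
#' @param newdata Tibble with `id` and `smiles` columns.
#' @return A tibble with `id`, `smiles`, `mu_ens`, `sigma2_ale`,
#'   `sigma2_epi`, `sigma2_total` and, in atom mode, an `atoms` list-column
#'   of per-atom tibbles (`atom_index`, `element`, `mu_atom`,
#'   `sigma2_ale_atom`, `sigma2_epi_atom`).
#' @export
ensemble_predict <- function(ensemble, newdata) {
  members <- as_member_list(ensemble)
  M <- length(members)
  modes <- unique(vapply(members, function(m) m$meta$mode, character(1)))
  if (length(modes) != 1) rlang::abort("all ensemble members must share one mode")
  graphs <- featurize_all(newdata$smiles)
  bad <- vapply(graphs, is.null, logical(1))
  if (any(bad)) {
    rlang::abort(sprintf(
      "unfeaturizable record(s): %s",
      paste(utils::head(newdata$id[bad], 5), collapse = ", ")
    ))
  }
  preds <- lapply(members, predict_on_graphs, graphs = graphs)
  mu_mat <- vapply(preds, `[[`, numeric(nrow(newdata)), "mu")
  v_mat <- vapply(preds, `[[`, numeric(nrow(newdata)), "sigma2")
  mom <- ensemble_moments(matrix(mu_mat, ncol = M), matrix(v_mat, ncol = M))
  out <- tibble::tibble(
    id = newdata$id, smiles = newdata$smiles,
    mu_ens = mom$mu_ens, sigma2_ale = mom$sigma2_ale,
    sigma2_epi = mom$sigma2_epi,
    sigma2_total = mom$sigma2_ale + mom$sigma2_epi
  )
  if (modes == "atom") {
    mu_a <- vapply(preds, `[[`, numeric(length(preds[[1]]$mu_atoms)), "mu_atoms")
    sig_a <- vapply(preds, `[[`, numeric(length(preds[[1]]$sigma_atoms)), "sigma_atoms")
    mu_a <- matrix(mu_a, ncol = M)
    sig_a <- matrix(sig_a, ncol = M)
    mu_atom_ens <- rowMeans(mu_a)
    ale_atom <- rowMeans(sig_a^2)
    epi_atom <- rowMeans((mu_a - mu_atom_ens)^2)
    mol_of_atom <- preds[[1]]$mol_of_atom
    element <- preds[[1]]$element
    out$atoms <- lapply(seq_len(nrow(out)), function(m) {
      r <- which(mol_of_atom == m)
      tibble::tibble(
        atom_index = seq_along(r) - 1L,
        element = element[r],
        mu_atom = mu_atom_ens[r],
        sigma2_ale_atom = ale_atom[r],
        sigma2_epi_atom = epi_atom[r]
      )
    })
  }
  out
}

as_member_list <- function(ensemble) {
  if (inherits(ensemble, "atomuq_ensemble")) {
    ensemble$members
  } else if (is.list(ensemble) && all(vapply(ensemble, inherits, logical(1), "atomuq_model"))) {
    ensemble
  } else {
    rlang::abort("expected an atomuq_ensemble or a list of atomuq_model objects")
  }
}

#' @export
predict.atomuq_ensemble <- function(object, newdata, ...) {
  ensemble_predict(object, newdata)
}

#' Per-atom uncertainty decomposition for one molecule
#'
#' Returns, for a single record, the ensemble-averaged atomic means and the
#' atomic aleatoric (`mean of member sigma_i^2`) and epistemic
#' (`population variance of member mu_i`) components. Covariance between
#' atoms is reported only at the molecule level.
#'
#' @param ensemble An atom-mode ensemble.
#' @param record One-row tibble with `id` and `smiles`.
#' @return A per-atom tibble (`atom_index`, `element`, `mu_atom`,
#'   `sigma2_ale_atom`, `sigma2_epi_atom`).
#' @export
decompose_atomic_uncertainty <- function(ensemble, record) {
  members <- as_member_list(ensemble)
  if (members[[1]]$meta$mode != "atom") {
    rlang::abort("atomic decomposition requires atom-based ensemble members")
  }
  stopifnot(nrow(record) == 1)
  ensemble_predict(ensemble, record)$atoms[[1]]
}

#' Inflate the predictive variances of all ensemble members
#'
#' Multiplies every member's predictive variance by `factor` exactly, via
#' the variance-layer log-scale parameter. Used to emulate an overestimated
#' aleatoric uncertainty before post-hoc calibration.
#'
#' @param ensemble An `atomuq_ensemble`.
#' @param factor Multiplicative variance inflation (> 0).
#' @return The modified ensemble.
#' @export
inflate_variance <- function(ensemble, factor) {
  stopifnot(factor > 0)
  ensemble$members <- lapply(ensemble$members, function(m) {
    m$par$log_scale <- m$par$log_scale + 0.5 * log(factor)
    m
  })
  ensemble
}

#' Post-hoc calibration of the ensemble aleatoric uncertainty
#'
#' Second round of training in which only the variance-layer weights of the
#' `M` members are relaxed; every other weight is frozen. The loss is the
#' mean heteroscedastic NLL of the ensemble mean and the ensemble aleatoric
#' variance against the calibration targets, optimized jointly over all
#' members' variance layers with early stopping on the validation ensemble
#' NLL (the state with the best validation NLL, including the incumbent, is
#' returned). The ensemble mean and the epistemic variance are untouched by
#' construction.
#'
#' @param ensemble A trained `atomuq_ensemble`.
#' @param train_data Calibration split (the training split by default
#'   convention).
#' @param valid_data Validation split for early stopping.
#' @param learning_rate,max_epochs,patience Full-batch Adam settings for the
#'   calibration round.
#' @return The calibrated ensemble, with `calibrated = TRUE` and a
#'   `calibration_history` tibble (per-epoch calibration and validation NLL).
#' @export
calibrate_ensemble <- function(ensemble, train_data, valid_data,
                               learning_rate = 0.01, max_epochs = 200,
                               patience = 15) {
  members <- as_member_list(ensemble)
  M <- length(members)
  if (M == 1) rlang::warn("calibrating a single-member ensemble; epistemic variance is 0")
  norm <- members[[1]]$norm
  same_norm <- all(vapply(members, function(m) {
    isTRUE(all.equal(m$norm, norm))
  }, logical(1)))
  if (!same_norm) rlang::abort("ensemble members must share target normalization")

  prep <- function(data) {
    graphs <- featurize_all(data$smiles)
    if (any(vapply(graphs, is.null, logical(1)))) {
      rlang::abort("all calibration SMILES must be featurizable")
    }
    bg <- batch_graphs(graphs)
    y_std <- (data$y - norm$mean) / norm$sd
    # frozen per-member quantities: trunk activations, molecular means,
    # correlation matrices (atom mode)
    frozen <- lapply(members, function(mod) {
      ep <- as_encoder_view(mod$par, mod$meta)
      hp <- as_head_view(mod$par, mod$meta)
      enc <- encoder_forward(bg, ep, keep_cache = FALSE)
      if (mod$meta$mode == "atom") {
        Fin <- enc$F
      } else {
        Fin <- rowsum(enc$F, bg$mol_of_atom)
      }
      Upre <- sweep(Fin %*% hp$W_t, 2, hp$b_t, "+")
      U <- relu(Upre)
      mu_rows <- drop(U %*% hp$w_mu) + hp$b_mu
      if (mod$meta$mode == "atom") {
        rows <- split(seq_len(bg$total_atoms), bg$mol_of_atom)
        Rlist <- lapply(rows, function(r) {
          pairwise_correlation(Fin[r, , drop = FALSE])
        })
        mu_m <- unname(drop(rowsum(mu_rows, bg$mol_of_atom)))
        list(U = U, rows = rows, R = Rlist, mu_m = mu_m, mode = "atom")
      } else {
        list(U = U, mu_m = mu_rows, mode = "molecule")
      }
    })
    mu_mat <- vapply(frozen, `[[`, numeric(bg$n_mols), "mu_m")
    list(bg = bg, y = y_std, frozen = frozen,
         mu_ens = rowMeans(matrix(mu_mat, ncol = M)))
  }
  cal <- prep(train_data)
  val <- prep(valid_data)

  # member variance forward from frozen trunk activations
  member_v <- function(fz, w) {
    raw <- drop(fz$U %*% w$w_vl) + w$b_vl
    if (fz$mode == "atom") {
      sigma <- exp(w$log_scale) * (softplus(raw) + .sigma_floor)
      v_raw <- vapply(seq_along(fz$rows), function(m) {
        r <- fz$rows[[m]]
        sum(sigma[r] * drop(fz$R[[m]] %*% sigma[r]))
      }, numeric(1))
      list(v_raw = v_raw, raw = raw, sigma = sigma)
    } else {
      v_raw <- exp(2 * w$log_scale) * (softplus(raw) + .sigma_floor)
      list(v_raw = v_raw, raw = raw)
    }
  }

  vl <- lapply(members, function(m) m$par[vl_param_names()])
  ens_nll <- function(set, vl_now) {
    vs <- vapply(seq_len(M), function(j) {
      pmax(member_v(set$frozen[[j]], vl_now[[j]])$v_raw, .var_floor)
    }, numeric(length(set$y)))
    ale <- rowMeans(matrix(vs, ncol = M))
    mean(heteroscedastic_nll(set$mu_ens, pmax(ale, .var_floor), set$y))
  }

  flat <- unlist(vl, recursive = FALSE)
  names(flat) <- paste0(rep(seq_len(M), each = 3), ".", names(flat))
  opt <- adam_init(flat, lr = learning_rate)
  best <- list(nll = ens_nll(val, vl), vl = vl, epoch = 0L)
  history <- list(tibble::tibble(epoch = 0L, cal_nll = ens_nll(cal, vl),
                                 valid_nll = best$nll))
  stale <- 0L
  B <- length(cal$y)
  for (epoch in seq_len(max_epochs)) {
    fwd <- lapply(seq_len(M), function(j) member_v(cal$frozen[[j]], vl[[j]]))
    v_members <- vapply(fwd, function(f) pmax(f$v_raw, .var_floor), numeric(B))
    v_members <- matrix(v_members, ncol = M)
    ale_raw <- rowMeans(v_members)
    ale <- pmax(ale_raw, .var_floor)
    nll <- heteroscedastic_nll(cal$mu_ens, ale, cal$y)
    loss <- mean(nll)
    g_ale <- (1 / (2 * ale) - (cal$y - cal$mu_ens)^2 / (2 * ale^2)) / B
    g_ale[ale_raw < .var_floor] <- 0
    grads <- list()
    for (j in seq_len(M)) {
      fz <- cal$frozen[[j]]
      f <- fwd[[j]]
      g_v <- g_ale / M
      g_v[f$v_raw < .var_floor] <- 0
      w <- vl[[j]]
      if (fz$mode == "atom") {
        g_sigma <- numeric(length(f$sigma))
        for (m in seq_along(fz$rows)) {
          r <- fz$rows[[m]]
          g_sigma[r] <- 2 * g_v[m] * drop(fz$R[[m]] %*% f$sigma[r])
        }
        g_raw <- g_sigma * exp(w$log_scale) * sigmoid(f$raw)
        g_ls <- sum(g_sigma * f$sigma)
      } else {
        g_raw <- g_v * exp(2 * w$log_scale) * sigmoid(f$raw)
        g_ls <- sum(2 * g_v * f$v_raw)
      }
      grads[[paste0(j, ".w_vl")]] <- crossprod(fz$U, g_raw)
      grads[[paste0(j, ".b_vl")]] <- sum(g_raw)
      grads[[paste0(j, ".log_scale")]] <- g_ls
    }
    upd <- adam_step(flat, grads, opt, clip = 10)
    flat <- upd$params; opt <- upd$state
    vl <- lapply(seq_len(M), function(j) {
      stats::setNames(flat[paste0(j, ".", vl_param_names())], vl_param_names())
    })
    v_nll <- ens_nll(val, vl)
    history[[epoch + 1L]] <- tibble::tibble(epoch = epoch, cal_nll = loss,
                                            valid_nll = v_nll)
    if (v_nll < best$nll) {
      best <- list(nll = v_nll, vl = vl, epoch = epoch)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale > patience) break
    }
  }
  for (j in seq_len(M)) {
    members[[j]]$par[vl_param_names()] <- best$vl[[j]]
  }
  if (inherits(ensemble, "atomuq_ensemble")) {
    ensemble$members <- members
  } else {
    ensemble <- structure(list(members = members, M = M,
                               mode = members[[1]]$meta$mode,
                               base_seed = NA_integer_, calibrated = FALSE),
                          class = "atomuq_ensemble")
  }
  ensemble$calibrated <- TRUE
  ensemble$calibration_history <- dplyr::bind_rows(history)
  ensemble
}

#' Save or load an ensemble directory
#'
#' Layout: `member_000.ckpt` ... `member_{M-1}.ckpt` (with JSON sidecars)
#' plus `ensemble.json` recording mode, M, seeds and calibration status.
#'
#' @param ensemble An `atomuq_ensemble`.
#' @param dir Directory path (created if needed).
#' @return `write_ensemble()` returns `dir` invisibly; `read_ensemble()`
#'   returns the ensemble.
#' @export
write_ensemble <- function(ensemble, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (j in seq_len(ensemble$M)) {
    write_checkpoint(ensemble$members[[j]],
                     file.path(dir, sprintf("member_%03d.ckpt", j - 1L)))
  }
  meta <- list(
    mode = ensemble$mode, M = ensemble$M, base_seed = ensemble$base_seed,
    seeds = vapply(ensemble$members, function(m) m$config$seed, integer(1)),
    calibrated = ensemble$calibrated
  )
  jsonlite::write_json(meta, file.path(dir, "ensemble.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "ensemble.json"), simplifyVector = TRUE)
  members <- lapply(seq_len(meta$M), function(j) {
    read_checkpoint(file.path(dir, sprintf("member_%03d.ckpt", j - 1L)))
  })
  structure(list(
    members = members, M = as.integer(meta$M), mode = meta$mode,
    base_seed = meta$base_seed, calibrated = isTRUE(meta$calibrated),
    calibration_history = NULL
  ), class = "atomuq_ensemble")
}

# Test hook: checksum of every non-variance-layer parameter block.
frozen_param_checksums <- function(ensemble) {
  lapply(as_member_list(ensemble), function(m) {
    p <- m$par[setdiff(names(m$par), vl_param_names())]
    vapply(p, function(x) sum(as.numeric(x) * seq_along(x)), numeric(1))
  })
}
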