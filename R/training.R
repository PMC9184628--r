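#' Training configuration
#'
#' Defaults follow the published recipe: Adam at learning rate 1e-3 with
#' no decay, L2 regularization with lambda = 1e-5 on weights (not
#' biases), an input-gradient (gradient norm) penalty that keeps the
#' logit's input gradients small so reference-based attributions stay
#' faithful, early stopping once the validation loss has not improved for
#' `patience` consecutive epochs, and exposure to training lengths 100,
#' 1000 and 10000 bp. The penalty coefficient is not published; 1e-4 is
#' the package default.
#'
#' @param learning_rate Adam step size.
#' @param l2_lambda L2 coefficient on weights.
#' @param input_grad_lambda coefficient on the mean squared input-gradient
#'   norm of the logit; 0 disables the (costly) penalty.
#' @param patience consecutive non-improving epochs tolerated before
#'   stopping; 0 stops at the first epoch without improvement.
#' @param max_epochs hard epoch cap.
#' @param batch_size reads per gradient step (batches are
#'   length-homogeneous).
#' @param training_lengths crop lengths used by [make_length_variants()].
#' @param seed master seed for shuffling (epoch-indexed).
#' @return A `training_config` list.
#' @export
training_config <- function(learning_rate = 1e-3, l2_lambda = 1e-5,
                            input_grad_lambda = 1e-4, patience = 30L,
                            max_epochs = 100L, batch_size = 64L,
                            training_lengths = c(100, 1000, 10000),
                            seed = 1L) {
  stopifnot(learning_rate > 0, l2_lambda >= 0, input_grad_lambda >= 0,
            patience >= 0, max_epochs >= 1, batch_size >= 1,
            length(training_lengths) >= 1)
  structure(list(learning_rate = learning_rate, l2_lambda = l2_lambda,
                 input_grad_lambda = input_grad_lambda,
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 training_lengths = as.integer(training_lengths),
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Assemble a labeled dataset
#'
#' @param bases character vector of sequences.
#' @param label integer vector in \{0, 1\} (1 = host).
#' @param provenance per-read origin tag (`"reference-derived"`,
#'   `"sequencer-derived"` or `"synthetic"`).
#' @return data.frame with columns `bases`, `label`, `provenance`.
#' @export
labeled_dataset <- function(bases, label, provenance = "synthetic") {
  stopifnot(length(bases) == length(label), all(label %in% c(0L, 1L)),
            all(nchar(bases) > 0))
  data.frame(bases = bases, label = as.integer(label),
             provenance = rep_len(provenance, length(bases)),
             stringsAsFactors = FALSE)
}

#' Expose a dataset to multiple lengths
#'
#' Emits, per source read and per training length it can support, one
#' uniformly positioned crop at that length carrying the source label.
#' Reads shorter than a target length contribute no variant there. Crop
#' positions are drawn reproducibly from `seed`.
#'
#' @param dataset data.frame with `bases` and `label`.
#' @param training_lengths target crop lengths (bp).
#' @param seed integer seed.
#' @return data.frame with `bases`, `label`, `length`, `source` (row index
#'   of the originating read).
#' @export
make_length_variants <- function(dataset,
                                 training_lengths = c(100, 1000, 10000),
                                 seed = 1L) {
  set.seed(seed)
  lens <- nchar(dataset$bases)
  out <- lapply(sort(training_lengths), function(tl) {
    idx <- which(lens >= tl)
    if (!length(idx)) return(NULL)
    start <- floor(runif(length(idx)) * (lens[idx] - tl + 1)) + 1
    data.frame(bases = substr(dataset$bases[idx], start, start + tl - 1),
               label = dataset$label[idx], length = tl, source = idx,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Sum of squared weights (excluding biases), for the L2 term.
.l2_sumsq <- function(model) {
  sum(vapply(model$weights$conv, function(l) sum(l$W^2), numeric(1))) +
    sum(model$weights$fc_w^2)
}

#' Training loss on one batch
#'
#' Mean binary cross-entropy plus `l2_lambda` times the sum of squared
#' weights plus `input_grad_lambda` times the mean squared norm of the
#' gradient of the logit with respect to the one-hot input.
#'
#' @param model a `host_cnn`.
#' @param batch character vector of equal-length sequences or an
#'   `N x L x 4` array.
#' @param labels integer labels in \{0, 1\}.
#' @param config a [training_config()].
#' @return Scalar loss.
#' @export
model_loss <- function(model, batch, labels, config = training_config()) {
  eb <- .engine_batch(model, batch)
  stopifnot(length(labels) == eb$N, all(labels %in% c(0, 1)))
  ea <- .engine_args(model)
  g <- cnn_grad_cpp(ea$W, ea$b, ea$fw, ea$fb, ea$k, ea$pool, eb$X, eb$L,
                    as.numeric(labels), FALSE, config$input_grad_lambda > 0)
  val <- g$bce + config$l2_lambda * .l2_sumsq(model) +
    config$input_grad_lambda * g$grad_penalty
  if (!is.finite(val))
    stop("non-finite training loss (bce = ", g$bce, ", grad penalty = ",
         g$grad_penalty, ")")
  val
}

# One Adam step over the flat list of parameter arrays.
.adam_step <- function(par, grad, st, lr, t, b1 = 0.9, b2 = 0.999,
                       eps = 1e-8) {
  for (nm in names(par)) {
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * grad[[nm]]
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * grad[[nm]]^2
    mhat <- st$m[[nm]] / (1 - b1^t)
    vhat <- st$v[[nm]] / (1 - b2^t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  par
}

.flatten_weights <- function(model) {
  w <- model$weights
  out <- list()
  for (i in seq_along(w$conv)) {
    out[[paste0("W", i)]] <- w$conv[[i]]$W
    out[[paste0("b", i)]] <- w$conv[[i]]$b
  }
  out$fw <- w$fc_w
  out$fb <- w$fc_b
  out
}

.unflatten_weights <- function(model, par) {
  for (i in seq_along(model$weights$conv)) {
    model$weights$conv[[i]]$W <- par[[paste0("W", i)]]
    model$weights$conv[[i]]$b <- par[[paste0("b", i)]]
  }
  model$weights$fc_w <- par$fw
  model$weights$fc_b <- par$fb
  model
}

# Encode a dataset into length-homogeneous engine groups.
.encode_groups <- function(dataset) {
  lens <- nchar(dataset$bases)
  lapply(split(seq_len(nrow(dataset)), lens), function(idx) {
    L <- lens[idx[1]]
    list(X = encode_seqs_cpp(dataset$bases[idx], L), L = L,
         y = as.numeric(dataset$label[idx]), n = length(idx))
  })
}

# Full loss over encoded groups without weight gradients.
.dataset_loss <- function(par, k, pool, groups, config, batch_size) {
  l2 <- config$l2_lambda * sum(unlist(lapply(names(par), function(nm)
    if (grepl("^W|^fw", nm)) sum(par[[nm]]^2) else 0)))
  nl <- sum(grepl("^W", names(par)))
  W <- lapply(seq_len(nl), function(i) par[[paste0("W", i)]])
  b <- lapply(seq_len(nl), function(i) par[[paste0("b", i)]])
  tot <- 0; n <- 0
  for (grp in groups) {
    for (bi in split(seq_len(grp$n), (seq_len(grp$n) - 1L) %/% batch_size)) {
      cols <- as.vector(outer(seq_len(grp$L), (bi - 1L) * grp$L, `+`))
      g <- cnn_grad_cpp(W, b, par$fw, par$fb, k, pool,
                        grp$X[, cols, drop = FALSE], grp$L, grp$y[bi],
                        FALSE, config$input_grad_lambda > 0)
      tot <- tot + length(bi) *
        (g$bce + config$input_grad_lambda * g$grad_penalty)
      n <- n + length(bi)
    }
  }
  tot / n + l2
}

#' Train the classifier
#'
#' Adam updates on length-homogeneous, class-shuffled batches with the
#' configured loss; after each epoch the validation loss is recorded, and
#' training stops once it has not improved for `patience` consecutive
#' epochs (or at `max_epochs`). The returned model carries the weights of
#' the best validation epoch. Fully reproducible from
#' (data, config, seed) on one device.
#'
#' @param model a `host_cnn` (its weights are the starting point).
#' @param train,val data.frames with `bases` and `label`, both classes
#'   present.
#' @param config a [training_config()].
#' @param verbose print per-epoch losses.
#' @return List with `model` (best weights) and `history` (data.frame of
#'   epoch, train_loss, val_loss).
#' @export
train_model <- function(model, train, val, config = training_config(),
                        verbose = FALSE) {
  stopifnot(inherits(model, "host_cnn"), inherits(config, "training_config"))
  for (d in list(train, val))
    if (!nrow(d) || length(unique(d$label)) < 2L)
      stop("train and val must be non-empty and contain both classes")
  k <- model$config$kernel_length
  pool <- model$config$pool_length
  tg <- .encode_groups(train)
  vg <- .encode_groups(val)

  par <- .flatten_weights(model)
  st <- new.env()
  st$m <- lapply(par, function(p) p * 0)
  st$v <- lapply(par, function(p) p * 0)
  nl <- model$config$num_conv_layers
  l2 <- config$l2_lambda
  gpl <- config$input_grad_lambda

  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best_val <- Inf
  best_par <- par
  wait <- 0L
  step <- 0L

  for (epoch in seq_len(config$max_epochs)) {
    set.seed(config$seed + epoch)
    tr_tot <- 0; tr_n <- 0
    for (grp in tg) {
      perm <- sample(grp$n)
      for (bi in split(perm, (seq_along(perm) - 1L) %/% config$batch_size)) {
        cols <- as.vector(outer(seq_len(grp$L), (bi - 1L) * grp$L, `+`))
        W <- lapply(seq_len(nl), function(i) par[[paste0("W", i)]])
        b <- lapply(seq_len(nl), function(i) par[[paste0("b", i)]])
        g <- cnn_grad_cpp(W, b, par$fw, par$fb, k, pool,
                          grp$X[, cols, drop = FALSE], grp$L, grp$y[bi],
                          TRUE, gpl > 0)
        grad <- list()
        for (i in seq_len(nl)) {
          grad[[paste0("W", i)]] <- g$gW[[i]] + 2 * l2 * W[[i]] +
            (if (gpl > 0) gpl * g$gpW[[i]] else 0)
          grad[[paste0("b", i)]] <- g$gb[[i]]
        }
        grad$fw <- g$gfw + 2 * l2 * par$fw +
          (if (gpl > 0) gpl * g$gpfw else 0)
        grad$fb <- g$gfb
        step <- step + 1L
        par <- .adam_step(par, grad, st, config$learning_rate, step)
        bl <- g$bce + gpl * g$grad_penalty
        tr_tot <- tr_tot + length(bi) * bl
        tr_n <- tr_n + length(bi)
      }
    }
    train_loss <- tr_tot / tr_n +
      l2 * sum(unlist(lapply(names(par), function(nm)
        if (grepl("^W|^fw", nm)) sum(par[[nm]]^2) else 0)))
    val_loss <- .dataset_loss(par, k, pool, vg, config, config$batch_size)
    if (!is.finite(train_loss) || !is.finite(val_loss))
      stop("non-finite loss at epoch ", epoch,
           " (train = ", train_loss, ", val = ", val_loss, ")")
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = train_loss,
                                         val_loss = val_loss))
    if (verbose)
      message(sprintf("epoch %d  train %.5f  val %.5f", epoch, train_loss,
                      val_loss))
    if (val_loss < best_val) {
      best_val <- val_loss
      best_par <- par
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= max(config$patience, 1L)) break
    }
  }
  list(model = .unflatten_weights(model, best_par), history = history)
}
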