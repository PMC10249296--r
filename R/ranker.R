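# The ranking model: twin graph encoders over the featurized reactant and
# product graphs, concatenated reaction representation, two-linear-layer
# scorer, pairwise label-smoothed cross-entropy training.

#' Encoder configuration
#'
#' @param hidden hidden width of both GNN backbones (default 200)
#' @param layers number of message-passing layers (default 3)
#' @param readout_steps global-attention readout iterations (default 2)
#' @param heads attention heads in the readout (default 1)
#' @param dropout dropout rate on the scorer hidden layer during training
#' @param schema feature schema the encoder is bound to
#' @return an `encoder_config`
#' @export
encoder_config <- function(hidden = 200L, layers = 3L, readout_steps = 2L,
                           heads = 1L, dropout = 0,
                           schema = reaction_feature_schema()) {
  if (hidden < 1L || layers < 1L || readout_steps < 0L || heads < 1L)
    rr_usage_error("encoder dimensions must be positive (readout_steps >= 0)")
  if (dropout < 0 || dropout >= 1) rr_usage_error("dropout must be in [0, 1)")
  structure(list(hidden = as.integer(hidden), layers = as.integer(layers),
                 readout_steps = as.integer(readout_steps),
                 heads = as.integer(heads), dropout = dropout,
                 schema_hash = schema_hash(schema)),
            class = "encoder_config")
}

#' Training configuration
#'
#' @param epsilon label-smoothing parameter in `[0, 0.5)`
#' @param lr Adam learning rate
#' @param batch_size pairs per gradient step
#' @param epochs training epochs
#' @param max_pairs training pairs sampled per product per epoch
#' @param seed RNG seed; a fixed seed makes the run reproducible
#' @param val_fraction fraction of products held out for validation when no
#'   separate validation lists are given
#' @param negative_mode `"resample"` draws fresh negatives every epoch,
#'   `"fixed"` fixes them once at the start
#' @return a `train_config`
#' @export
train_config <- function(epsilon = 0.1, lr = 1e-3, batch_size = 32L,
                         epochs = 20L, max_pairs = 4L, seed = 1L,
                         val_fraction = 0.1,
                         negative_mode = c("resample", "fixed")) {
  if (epsilon < 0 || epsilon >= 0.5) rr_usage_error("epsilon must be in [0, 0.5)")
  if (lr <= 0 || batch_size < 1L || epochs < 0L || max_pairs < 1L)
    rr_usage_error("lr, batch_size, max_pairs must be positive; epochs >= 0")
  if (val_fraction < 0 || val_fraction >= 1)
    rr_usage_error("val_fraction must be in [0, 1)")
  structure(list(epsilon = epsilon, lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), max_pairs = as.integer(max_pairs),
                 seed = as.integer(seed), val_fraction = val_fraction,
                 negative_mode = match.arg(negative_mode)),
            class = "train_config")
}

rr_param_shapes <- function(cfg, d_in, d_e, scorer_hidden = NULL) {
  h <- cfg$hidden; L <- cfg$layers; T <- cfg$readout_steps; A <- cfg$heads
  c_h <- if (is.null(scorer_hidden)) h else scorer_hidden
  shapes <- list()
  for (s in c("r", "p")) {
    shapes[[paste0(s, "_Win")]] <- c(h, d_in)
    shapes[[paste0(s, "_bin")]] <- c(h, 1)
    for (l in seq_len(L)) {
      shapes[[paste0(s, "_Wg", l)]] <- c(h, 2 * h + d_e)
      shapes[[paste0(s, "_bg", l)]] <- c(h, 1)
      shapes[[paste0(s, "_Wm", l)]] <- c(h, h)
      shapes[[paste0(s, "_Wf", l)]] <- c(h, d_e)
      shapes[[paste0(s, "_bm", l)]] <- c(h, 1)
      shapes[[paste0(s, "_Wu", l)]] <- c(h, h)
      shapes[[paste0(s, "_bu", l)]] <- c(h, 1)
    }
    for (t in seq_len(T)) {
      shapes[[paste0(s, "_Wq", t)]] <- c(A * h, h)
      shapes[[paste0(s, "_Wz", t)]] <- c(h, 2 * h)
      shapes[[paste0(s, "_bz", t)]] <- c(h, 1)
    }
  }
  shapes[["sc_W1"]] <- c(c_h, 2 * h)
  shapes[["sc_b1"]] <- c(c_h, 1)
  shapes[["sc_w2"]] <- c(1, c_h)
  shapes[["sc_b2"]] <- c(1, 1)
  shapes
}

#' Initialize a ranking model
#'
#' Glorot-uniform weights drawn from R's RNG (seed it with [set.seed()] for a
#' reproducible initialization), zero biases.
#'
#' @param config an `encoder_config`
#' @param schema feature schema the model will consume
#' @return a `ranker_model`
#' @export
init_ranker <- function(config = encoder_config(),
                        schema = reaction_feature_schema()) {
  shapes <- rr_param_shapes(config, schema$d_atom, schema$d_bond)
  params <- lapply(names(shapes), function(nm) {
    sh <- shapes[[nm]]
    if (sh[2] == 1 || grepl("^(r|p)_b|^sc_b", nm)) {
      matrix(0, nrow = sh[1], ncol = sh[2])
    } else {
      lim <- sqrt(6 / (sh[1] + sh[2]))
      matrix(stats::runif(prod(sh), -lim, lim), nrow = sh[1], ncol = sh[2])
    }
  })
  names(params) <- names(shapes)
  params$dims <- as.integer(c(config$hidden, config$layers,
                              config$readout_steps, config$heads))
  structure(list(params = params, encoder_config = config,
                 schema = schema, schema_hash = schema_hash(schema),
                 train_config = NULL, log = NULL),
            class = "ranker_model")
}

#' @export
print.ranker_model <- function(x, ...) {
  cfg <- x$encoder_config
  np <- sum(vapply(x$params[names(x$params) != "dims"], length, numeric(1)))
  cat(sprintf("<ranker_model> hidden %d, %d MP layers, %d readout steps, %d head(s); %d parameters%s\n",
              cfg$hidden, cfg$layers, cfg$readout_steps, cfg$heads, np,
              if (is.null(x$log)) " (untrained)" else ""))
  invisible(x)
}

# ---- graph sets ---------------------------------------------------------

#' Featurize prediction lists into a scoring-ready graph set
#'
#' Builds the paired numeric graphs for every scorable candidate of every
#' list once, and holds them in an in-memory store the C++ encoder reads
#' directly. The returned index maps (list, candidate) to store ids;
#' unscorable candidates get id `NA`.
#'
#' @param lists list of `prediction_list`
#' @param radius neighborhood radius for the change annotation
#' @param progress print a note every 500 lists
#' @return an `rr_graph_set`
#' @export
featurize_predictions <- function(lists, radius = 1L, progress = FALSE) {
  schema <- reaction_feature_schema()
  graphs <- list()
  rows <- list()
  n_id <- 0L
  for (li in seq_along(lists)) {
    pl <- lists[[li]]
    for (ci in seq_along(pl$candidates)) {
      r <- pl$candidates[[ci]]
      id <- NA_integer_
      if (r$scorable && sum(r$product$map > 0L) > 0L) {
        fg <- build_reaction_graphs(r, radius = radius)
        n_id <- n_id + 1L
        graphs[[n_id]] <- list(xr = fg$reactant$x, er = fg$reactant$edges,
                               fr = fg$reactant$ef, xp = fg$product$x,
                               ep = fg$product$edges, fp = fg$product$ef)
        id <- n_id
      }
      rows[[length(rows) + 1L]] <- data.frame(
        list = li, cand = ci, rank = r$original_rank,
        recorded = isTRUE(r$is_recorded), store_id = id)
    }
    if (progress && li %% 500L == 0L)
      message(sprintf("featurized %d / %d lists", li, length(lists)))
  }
  index <- do.call(rbind, rows)
  structure(list(store = rr_store_create(graphs), index = index,
                 schema_hash = schema_hash(schema), radius = radius),
            class = "rr_graph_set")
}

check_schema <- function(model, hash) {
  if (!identical(model$schema_hash, hash))
    rr_schema_error("feature schema of the graphs does not match the model")
}

#' Reaction embedding of a featurized reaction
#'
#' Concatenation of the two encoder outputs (length `2 * hidden`); invariant
#' under atom-order permutations of the input graphs.
#'
#' @param model a `ranker_model`
#' @param graphs a `featurized_reaction_graph`
#' @return numeric vector
#' @export
encode_reaction <- function(model, graphs) {
  check_schema(model, graphs$schema_hash)
  store <- rr_store_create(list(list(
    xr = graphs$reactant$x, er = graphs$reactant$edges, fr = graphs$reactant$ef,
    xp = graphs$product$x, ep = graphs$product$edges, fp = graphs$product$ef)))
  as.numeric(rr_encode_id(model$params, store, 1L))
}

#' Ranking score of a featurized reaction
#'
#' Deterministic in eval mode (no dropout is applied at inference).
#'
#' @param model a `ranker_model`
#' @param graphs a `featurized_reaction_graph`
#' @return finite numeric scalar
#' @export
score_candidate <- function(model, graphs) {
  check_schema(model, graphs$schema_hash)
  store <- rr_store_create(list(list(
    xr = graphs$reactant$x, er = graphs$reactant$edges, fr = graphs$reactant$ef,
    xp = graphs$product$x, ep = graphs$product$edges, fp = graphs$product$ef)))
  as.numeric(rr_score_ids(model$params, store, 1L))
}

#' Pairwise label-smoothed cross-entropy loss
#'
#' Two-class cross-entropy of the softmax over `(s_pos, s_neg)` against the
#' smoothed target `(1 - epsilon, epsilon)`. At equal scores the loss is
#' `log(2)` for every epsilon; for `epsilon > 0` the minimum sits at margin
#' `log((1 - epsilon) / epsilon)`.
#'
#' @param s_pos score of the recorded (positive) candidate
#' @param s_neg score of the non-recorded candidate
#' @param epsilon label smoothing in `[0, 0.5)`
#' @return numeric loss (vectorized over margins)
#' @export
pairwise_loss <- function(s_pos, s_neg, epsilon = 0.1) {
  if (any(epsilon < 0) || any(epsilon >= 0.5))
    rr_usage_error("epsilon must be in [0, 0.5)")
  delta <- s_pos - s_neg
  log_sig <- function(x) ifelse(x >= 0, -log1p(exp(-x)), x - log1p(exp(x)))
  -(1 - epsilon) * log_sig(delta) - epsilon * log_sig(-delta)
}

#' Build training pairs from prediction lists
#'
#' For each product with a recorded candidate, up to `max_pairs` tuples
#' (recorded, sampled non-recorded); the sampling is seeded. Lists without a
#' recorded candidate contribute nothing; their count is reported as an
#' attribute.
#'
#' @param lists list of `prediction_list`
#' @param max_pairs pairs per product
#' @param seed RNG seed
#' @return list of `list(positive = , negative = )` record pairs, with
#'   attribute `skipped` counting lists without a recorded candidate
#' @export
make_training_pairs <- function(lists, max_pairs = 4L, seed = 1L) {
  idx <- make_pair_ids(lists, max_pairs, seed)
  pairs <- lapply(seq_len(nrow(idx)), function(i) {
    list(positive = lists[[idx$list[i]]]$candidates[[idx$pos[i]]],
         negative = lists[[idx$list[i]]]$candidates[[idx$neg[i]]])
  })
  attr(pairs, "skipped") <- attr(idx, "skipped")
  pairs
}

# id-level version used by the trainer: data.frame(list, pos, neg) of
# candidate positions within each list
make_pair_ids <- function(lists, max_pairs, seed) {
  set.seed(seed)
  skipped <- 0L
  out <- vector("list", length(lists))
  for (li in seq_along(lists)) {
    pl <- lists[[li]]
    rec <- which(vapply(pl$candidates, function(r) isTRUE(r$is_recorded), logical(1)))
    if (length(rec) != 1L) { skipped <- skipped + 1L; next }
    scor <- vapply(pl$candidates, function(r) r$scorable, logical(1))
    negs <- setdiff(which(scor), rec)
    if (length(negs) == 0L) { skipped <- skipped + 1L; next }
    take <- if (length(negs) <= max_pairs) negs else sort(sample(negs, max_pairs))
    out[[li]] <- data.frame(list = li, pos = rec, neg = take)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(list = integer(0), pos = integer(0), neg = integer(0))
  attr(res, "skipped") <- skipped
  res
}

adam_init <- function(params) {
  lapply(params, function(p) if (is.matrix(p)) list(m = p * 0, v = p * 0) else NULL)
}

adam_step <- function(params, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(params)) {
    if (!is.matrix(params[[nm]])) next
    g <- grads[[nm]]
    st <- state[[nm]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g * g
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    state[[nm]] <- st
  }
  list(params = params, state = state)
}

# pairwise accuracy of a model over the (recorded, non-recorded) pairs of a
# set of lists, given their graph set
pairwise_accuracy <- function(params, gset, lists) {
  idx <- gset$index
  scores <- rep(NA_real_, nrow(idx))
  ok <- !is.na(idx$store_id)
  if (any(ok)) scores[ok] <- rr_score_ids(params, gset$store, idx$store_id[ok])
  scores[!ok] <- -Inf
  accs <- c()
  for (li in unique(idx$list)) {
    sub <- idx$list == li
    rec <- which(idx$recorded[sub])
    if (length(rec) != 1L) next
    s <- scores[sub]
    accs <- c(accs, mean(s[rec] > s[-rec]))
  }
  if (length(accs) == 0L) return(NA_real_)
  mean(accs)
}

#' Train a ranking model
#'
#' Pairwise training: every gradient step pushes the recorded candidate's
#' score above a sampled non-recorded candidate's under the label-smoothed
#' cross-entropy. Negatives are re-sampled every epoch by default (seeded).
#' The returned model carries the parameters of the epoch with the best
#' validation pairwise accuracy and a per-epoch training log.
#'
#' @param lists training `prediction_list`s (must contain recorded candidates)
#' @param config an `encoder_config`
#' @param train a `train_config`
#' @param val_lists optional held-out lists; when `NULL`, `val_fraction` of
#'   the training products is held out
#' @param gset optional prebuilt [featurize_predictions()] graph set covering
#'   `lists` (built here when missing)
#' @param val_gset optional graph set for `val_lists`
#' @param verbose print per-epoch progress
#' @return a trained `ranker_model`
#' @export
train_ranker <- function(lists, config = encoder_config(), train = train_config(),
                         val_lists = NULL, gset = NULL, val_gset = NULL,
                         verbose = FALSE) {
  if (length(lists) == 0L) rr_usage_error("no training lists")
  if (is.null(gset)) gset <- featurize_predictions(lists)

  set.seed(train$seed)
  model <- init_ranker(config)
  if (is.null(val_lists)) {
    n <- length(lists)
    nval <- max(1L, floor(train$val_fraction * n))
    val_ids <- sort(sample(n, nval))
    train_ids <- setdiff(seq_len(n), val_ids)
  } else {
    if (is.null(val_gset)) val_gset <- featurize_predictions(val_lists)
    train_ids <- seq_along(lists)
    val_ids <- integer(0)
  }

  params <- model$params
  state <- adam_init(params)
  tstep <- 0L

  subset_gset <- function(ids) {
    idx <- gset$index[gset$index$list %in% ids, , drop = FALSE]
    list(store = gset$store, index = idx, schema_hash = gset$schema_hash)
  }
  val_eval <- if (is.null(val_lists)) subset_gset(val_ids) else val_gset

  # vectorized (list, candidate) -> store id lookup
  lut_keys <- paste(gset$index$list, gset$index$cand)
  lookup_ids <- function(li, ci) {
    gset$index$store_id[match(paste(li, ci), lut_keys)]
  }

  fixed_pairs <- NULL
  log <- data.frame()
  best <- list(acc = -Inf, params = params)

  if (train$epochs == 0L) {
    model$params <- params
    model$train_config <- train
    model$log <- log
    return(model)
  }

  for (ep in seq_len(train$epochs)) {
    if (train$negative_mode == "fixed") {
      if (is.null(fixed_pairs))
        fixed_pairs <- make_pair_ids(lists[train_ids], train$max_pairs, train$seed)
      pid <- fixed_pairs
    } else {
      pid <- make_pair_ids(lists[train_ids], train$max_pairs, train$seed + ep)
    }
    if (nrow(pid) == 0L) rr_usage_error("no usable training pairs")
    pos_store <- lookup_ids(train_ids[pid$list], pid$pos)
    neg_store <- lookup_ids(train_ids[pid$list], pid$neg)
    keep <- !is.na(pos_store) & !is.na(neg_store)
    pos_store <- pos_store[keep]; neg_store <- neg_store[keep]

    set.seed(train$seed * 1000L + ep)
    ord <- sample(length(pos_store))
    pos_store <- pos_store[ord]; neg_store <- neg_store[ord]

    ep_loss <- 0; ep_acc <- 0; nb <- 0L
    bs <- train$batch_size
    for (b0 in seq(1, length(pos_store), by = bs)) {
      b1 <- min(b0 + bs - 1L, length(pos_store))
      res <- rr_pair_batch_grad(params, gset$store,
                                pos_store[b0:b1], neg_store[b0:b1],
                                train$epsilon,
                                dropout = config$dropout,
                                seed = train$seed + 7919L * ep + b0)
      tstep <- tstep + 1L
      upd <- adam_step(params, res$grads, state, train$lr, tstep)
      params <- upd$params; state <- upd$state
      ep_loss <- ep_loss + res$loss * (b1 - b0 + 1L)
      ep_acc <- ep_acc + res$accuracy * (b1 - b0 + 1L)
      nb <- nb + (b1 - b0 + 1L)
    }
    vacc <- pairwise_accuracy(params, val_eval,
                              if (is.null(val_lists)) lists[val_ids] else val_lists)
    log <- rbind(log, data.frame(epoch = ep, loss = ep_loss / nb,
                                 train_pairwise_acc = ep_acc / nb,
                                 val_pairwise_acc = vacc))
    if (!is.na(vacc) && vacc >= best$acc) best <- list(acc = vacc, params = params)
    if (verbose)
      message(sprintf("epoch %d: loss %.4f, train acc %.3f, val acc %.3f",
                      ep, ep_loss / nb, ep_acc / nb, vacc))
  }

  model$params <- best$params
  model$train_config <- train
  model$log <- log
  model
}

#' Score every candidate of each prediction list
#'
#' Adds an `rr_score` field to every candidate; unscorable sentinel
#' candidates get `-Inf`, the documented minimum.
#'
#' @param model a trained `ranker_model`
#' @param lists list of `prediction_list`
#' @param gset optional prebuilt graph set for `lists`
#' @return the lists with `rr_score` set on each candidate
#' @export
score_predictions <- function(model, lists, gset = NULL) {
  if (is.null(gset)) gset <- featurize_predictions(lists)
  check_schema(model, gset$schema_hash)
  idx <- gset$index
  scores <- rep(-Inf, nrow(idx))
  ok <- !is.na(idx$store_id)
  if (any(ok)) scores[ok] <- rr_score_ids(model$params, gset$store, idx$store_id[ok])
  for (i in seq_len(nrow(idx))) {
    lists[[idx$list[i]]]$candidates[[idx$cand[i]]]$rr_score <- scores[i]
  }
  lists
}

# ---- checkpoints --------------------------------------------------------

#' Save a ranking model to a single-file JSON checkpoint
#'
#' The checkpoint carries the parameters, both configs, the feature schema
#' and its hash, so schema compatibility can be verified on load.
#'
#' @param model a `ranker_model`
#' @param path output path
#' @export
save_ranker <- function(model, path) {
  obj <- list(
    params = lapply(model$params[names(model$params) != "dims"], identity),
    dims = model$params$dims,
    encoder_config = unclass(model$encoder_config),
    train_config = if (is.null(model$train_config)) NULL else unclass(model$train_config),
    schema = list(atom = model$schema$atom, bond = model$schema$bond,
                  element_vocab = model$schema$element_vocab),
    schema_hash = model$schema_hash,
    log = model$log
  )
  writeLines(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                           null = "null")), path)
  invisible(path)
}

#' Load a ranking model checkpoint
#' @param path checkpoint path written by [save_ranker()]
#' @return a `ranker_model`
#' @export
load_ranker <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  params <- lapply(obj$params, function(p) {
    m <- as.matrix(p)
    storage.mode(m) <- "double"
    m
  })
  params$dims <- as.integer(obj$dims)
  schema <- reaction_feature_schema()
  if (!identical(unname(schema_hash(schema)), unname(obj$schema_hash)))
    rr_schema_error("checkpoint was written under a different feature schema")
  cfg <- obj$encoder_config
  config <- encoder_config(cfg$hidden, cfg$layers, cfg$readout_steps,
                           cfg$heads, cfg$dropout)
  structure(list(params = params, encoder_config = config, schema = schema,
                 schema_hash = obj$schema_hash,
                 train_config = obj$train_config,
                 log = obj$log),
            class = "ranker_model")
}
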