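#' Experiment configuration
#'
#' Defaults mirror the factorial identification protocol: ten time delays
#' (2--36 ms) crossed with five grid densities (16--256 partitions) for 50
#' combinations, portraits resized to `out_pixels` square, 75 training
#' epochs of Adam on cross-entropy with dropout 0.5, and a chronological
#' 100/25 train/validation split of each subject's beats.
#'
#' @param tau_list Time delays, ms.
#' @param grid_list Grid partition counts.
#' @param out_pixels Portrait image size fed to the network.
#' @param arch `"original"` (256 x 256 input) or `"scaled"` (32 x 32).
#' @param epochs Training epochs.
#' @param dropout Drop probability on the classifier's hidden layers.
#' @param train_beats,val_beats Per-subject beat budget for the split.
#' @param optimizer Only `"adam"` is implemented.
#' @param learning_rate Adam step size.
#' @param batch_size Minibatch size.
#' @param seed Integer seed governing weight init, shuffling, dropout.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(tau_list = c(2, 4, 8, 12, 16, 20, 24, 28, 32, 36),
                              grid_list = c(16, 32, 64, 128, 256),
                              out_pixels = 256,
                              arch = c("original", "scaled"),
                              epochs = 75, dropout = 0.5,
                              train_beats = 100, val_beats = 25,
                              optimizer = "adam", learning_rate = 1e-3,
                              batch_size = 32, seed = 0) {
  arch <- match.arg(arch)
  stopifnot(epochs >= 0, all(tau_list > 0), all(grid_list >= 2),
            train_beats >= 1, val_beats >= 1, identical(optimizer, "adam"))
  structure(list(tau_list = tau_list, grid_list = grid_list,
                 out_pixels = out_pixels, arch = arch, epochs = epochs,
                 dropout = dropout, train_beats = train_beats,
                 val_beats = val_beats, optimizer = optimizer,
                 learning_rate = learning_rate, batch_size = batch_size,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Split each subject's beats chronologically into train and validation
#'
#' The first `train_n` beats of every subject go to training and the next
#' `val_n` to validation; later beats are unused and no shuffling crosses
#' the boundary. Subjects with fewer than `train_n + val_n` beats are
#' dropped with a message.
#'
#' @param beats Beat (or portrait) tibble with `subject_id` and `beat`
#'   columns.
#' @param train_n,val_n Beats per subject in each part.
#' @return List with tibbles `train` and `validation`.
#' @export
split_beats <- function(beats, train_n = 100, val_n = 25) {
  stopifnot(is.data.frame(beats), all(c("subject_id", "beat") %in%
                                        names(beats)))
  counts <- dplyr::count(beats, .data$subject_id)
  short <- counts$subject_id[counts$n < train_n + val_n]
  if (length(short)) {
    message("dropping ", length(short), " subject(s) with fewer than ",
            train_n + val_n, " beats: ", paste(short, collapse = ", "))
  }
  kept <- dplyr::filter(beats, !(.data$subject_id %in% short))
  kept <- dplyr::arrange(kept, .data$subject_id, .data$beat)
  ranked <- dplyr::mutate(dplyr::group_by(kept, .data$subject_id),
                          .rank = dplyr::row_number())
  ranked <- dplyr::ungroup(ranked)
  list(
    train = dplyr::select(dplyr::filter(ranked, .data$.rank <= train_n),
                          -".rank"),
    validation = dplyr::select(
      dplyr::filter(ranked, .data$.rank > train_n &
                      .data$.rank <= train_n + val_n), -".rank")
  )
}

#' Train a biometric network on portrait data
#'
#' Minibatch Adam on cross-entropy loss with per-epoch reshuffling of the
#' training set and inverted dropout on the classifier's hidden layers.
#' After every epoch the model is scored on the validation portraits;
#' the whole run is deterministic given `config$seed` (weight
#' initialization, shuffling and dropout all draw from one seeded
#' stream).
#'
#' @param train,validation Portrait tibbles (from
#'   [portraits_from_beats()] + [split_beats()]) with `subject_id` and a
#'   `portrait` list-column.
#' @param spec A `network_spec` whose input size matches the portraits
#'   and whose class count matches the number of subjects; by default
#'   built from `config$arch` and the data.
#' @param config An [experiment_config()].
#' @return A `psr_model`: list with the fitted `model` (`cnn_model`),
#'   `classes` (subject labels in class order), `trace` (tibble `epoch`,
#'   `val_accuracy`), and `config`.
#' @export
train_model <- function(train, validation, spec = NULL,
                        config = experiment_config()) {
  stopifnot(is.data.frame(train), "portrait" %in% names(train),
            is.data.frame(validation), "portrait" %in% names(validation))
  classes <- sort(unique(train$subject_id))
  if (length(classes) < 2) stop("training data must contain >= 2 subjects")
  missing_val <- setdiff(unique(validation$subject_id), classes)
  if (length(missing_val)) {
    stop("validation subjects absent from training: ",
         paste(missing_val, collapse = ", "))
  }
  counts <- table(factor(train$subject_id, classes))
  if (any(counts == 0)) stop("every class needs at least one training portrait")

  x_tr <- portraits_to_matrix(train$portrait)
  y_tr <- match(train$subject_id, classes)
  x_va <- portraits_to_matrix(validation$portrait)
  y_va <- match(validation$subject_id, classes)

  if (is.null(spec)) {
    spec <- if (config$arch == "scaled") build_scaled_spec(length(classes))
    else build_original_spec(length(classes))
    spec$layers <- purrr::map(spec$layers, function(l) {
      if (l$kind == "dropout") l$p <- config$dropout
      l
    })
  }
  if (spec$num_classes != length(classes)) {
    stop("spec has ", spec$num_classes, " classes but data has ",
         length(classes))
  }
  px <- sqrt(nrow(x_tr))
  if (!identical(as.integer(spec$input_shape[1:2]), as.integer(c(px, px)))) {
    stop("portrait size ", px, " does not match network input ",
         spec$input_shape[1])
  }

  n <- ncol(x_tr)
  trace <- numeric(config$epochs)
  withr::with_seed(config$seed, {
    model <- init_model_inplace(spec)
    state <- adam_init(model)
    t <- 0L
    if (config$epochs >= 1) {
      for (epoch in seq_len(config$epochs)) {
        perm <- sample.int(n)
        starts <- seq(1, n, by = config$batch_size)
        for (s in starts) {
          ids <- perm[s:min(s + config$batch_size - 1L, n)]
          fw <- forward_pass(model, x_tr[, ids, drop = FALSE],
                             training = TRUE)
          grads <- backward_pass(model, fw$caches,
                                 ce_grad(fw$out, y_tr[ids]))
          t <- t + 1L
          adam_step(model, grads, state, t, lr = config$learning_rate)
        }
        trace[epoch] <- accuracy_pct(model, x_va, y_va)
      }
    }
  })
  structure(list(model = model, classes = classes,
                 trace = tibble::tibble(epoch = seq_len(config$epochs),
                                        val_accuracy = trace),
                 config = config),
            class = "psr_model")
}

# weight init drawing from the *current* RNG stream (train_model already
# runs under with_seed, so a nested reseed would decouple init from config)
init_model_inplace <- function(spec) {
  seed_now <- sample.int(.Machine$integer.max, 1)
  init_model(spec, seed_now)
}

accuracy_pct <- function(model, x, y, batch = 128L) {
  if (length(y) == 0) stop("empty evaluation set")
  correct <- 0L
  for (s in seq(1, length(y), by = batch)) {
    ids <- s:min(s + batch - 1L, length(y))
    p <- forward_pass(model, x[, ids, drop = FALSE], training = FALSE)$out
    correct <- correct + sum(max.col(t(p), ties.method = "first") == y[ids])
  }
  100 * correct / length(y)
}

#' Identification accuracy of a fitted model on labelled portraits
#'
#' Accuracy is the percentage of portraits whose arg-max predicted class
#' matches the true subject label.
#'
#' @param object A `psr_model` from [train_model()].
#' @param portraits Portrait tibble with `subject_id` and `portrait`.
#' @return Accuracy in percent.
#' @export
evaluate_model <- function(object, portraits) {
  stopifnot(inherits(object, "psr_model"), is.data.frame(portraits),
            "portrait" %in% names(portraits))
  if (nrow(portraits) == 0) stop("empty evaluation set")
  x <- portraits_to_matrix(portraits$portrait)
  y <- match(portraits$subject_id, object$classes)
  if (anyNA(y)) stop("portraits contain subjects unknown to the model")
  accuracy_pct(object$model, x, y)
}

#' @export
print.psr_model <- function(x, ...) {
  cat(sprintf(
    "<psr_model> %d classes, %d epochs, final validation accuracy %.2f%%\n",
    length(x$classes), nrow(x$trace),
    utils::tail(x$trace$val_accuracy, 1)))
  invisible(x)
}

#' Stage-averaged accuracy over the four training stages
#'
#' Averages a per-epoch accuracy trace over the four 15-epoch blocks
#' 16--30, 31--45, 46--60 and 61--75 (1-based, inclusive). Traces shorter
#' than 75 epochs report only the complete stages.
#'
#' @param trace Numeric vector of per-epoch accuracies, or a tibble with
#'   `epoch` and `val_accuracy` columns (e.g. `psr_model$trace`).
#' @return Tibble with `stage` (label), `epochs` (range label), and
#'   `mean_accuracy`.
#' @examples
#' stage_averages(rep(100, 75))
#' @export
stage_averages <- function(trace) {
  if (is.data.frame(trace)) {
    trace <- trace$val_accuracy[order(trace$epoch)]
  }
  bounds <- list(`16~30` = 16:30, `31~45` = 31:45,
                 `46~60` = 46:60, `61~75` = 61:75)
  complete <- purrr::keep(bounds, ~ max(.x) <= length(trace))
  tibble::tibble(
    stage = seq_along(complete),
    epochs = names(complete),
    mean_accuracy = unname(purrr::map_dbl(complete, ~ mean(trace[.x])))
  )
}

#' Enumerate the factorial sweep cells of a configuration
#'
#' @param config An [experiment_config()].
#' @return Tibble with one row per (time delay, grid) combination, in
#'   sweep order.
#' @examples
#' nrow(sweep_cells(experiment_config()))  # 50
#' @export
sweep_cells <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  tidyr::expand_grid(tau_ms = config$tau_list, grid = config$grid_list)
}

#' Run the time-delay by grid-density factorial sweep
#'
#' For every pair in `config$tau_list` x `config$grid_list`, regenerates
#' portraits from the preprocessed beats, splits them chronologically,
#' trains the configured network, and records the per-epoch validation
#' accuracy. A failing cell is recorded with its error message and the
#' sweep continues.
#'
#' @param beats Preprocessed beat tibble ([preprocess_cohort()]), or a
#'   cohort tibble with a `record` list-column (preprocessed on the fly).
#' @param config An [experiment_config()].
#' @param fs Sampling rate of the beats, Sa/s.
#' @param spec_builder Optional `function(num_classes)` returning the
#'   `network_spec` to train; by default the architecture named by
#'   `config$arch`.
#' @return A `psr_sweep`: list with `results` (tibble `tau_ms`, `grid`,
#'   `epoch`, `val_accuracy`), `stages` (tibble `tau_ms`, `grid`,
#'   `stage`, `epochs`, `mean_accuracy`), `failed` (tibble `tau_ms`,
#'   `grid`, `reason`), and `config`.
#' @export
run_sweep <- function(beats, config = experiment_config(), fs = 1000,
                      spec_builder = NULL) {
  if (is.data.frame(beats) && "record" %in% names(beats)) {
    # relaxed sweep-mode screening: a subject qualifies whenever it can
    # fill the train/validation beat budget; apply preprocess_cohort()
    # yourself first for the strict duration rule
    beats <- preprocess_cohort(beats, min_duration_s = 0,
                               min_beats = config$train_beats +
                                 config$val_beats)
  }
  stopifnot(is.data.frame(beats), "samples" %in% names(beats))
  cells <- sweep_cells(config)
  results <- list()
  stages <- list()
  failed <- list()
  for (i in seq_len(nrow(cells))) {
    tau <- cells$tau_ms[i]
    grid <- cells$grid[i]
    res <- tryCatch({
      portraits <- portraits_from_beats(beats, tau_ms = tau,
                                        partitions = grid,
                                        out_pixels = config$out_pixels,
                                        fs = fs)
      parts <- split_beats(portraits, config$train_beats, config$val_beats)
      spec <- if (is.null(spec_builder)) NULL else
        spec_builder(length(unique(parts$train$subject_id)))
      train_model(parts$train, parts$validation, spec = spec,
                  config = config)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed[[length(failed) + 1]] <-
        tibble::tibble(tau_ms = tau, grid = grid,
                       reason = conditionMessage(res))
      next
    }
    results[[length(results) + 1]] <-
      dplyr::mutate(res$trace, tau_ms = tau, grid = grid,
                    .before = "epoch")
    stages[[length(stages) + 1]] <-
      dplyr::mutate(stage_averages(res$trace), tau_ms = tau, grid = grid,
                    .before = "stage")
  }
  structure(list(results = dplyr::bind_rows(results),
                 stages = dplyr::bind_rows(stages),
                 failed = dplyr::bind_rows(failed),
                 config = config),
            class = "psr_sweep")
}

#' @export
print.psr_sweep <- function(x, ...) {
  n_cells <- nrow(dplyr::distinct(x$results, .data$tau_ms, .data$grid))
  cat(sprintf("<psr_sweep> %d completed cell(s), %d failed, %d epochs each\n",
              n_cells, nrow(x$failed), x$config$epochs))
  if (nrow(x$stages)) {
    last <- dplyr::filter(x$stages, .data$stage == max(.data$stage))
    print(tidyr::pivot_wider(
      dplyr::select(last, "tau_ms", "grid", "mean_accuracy"),
      names_from = "grid", values_from = "mean_accuracy"), ...)
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted biometric model or a sweep
#'
#' `tidy()` on a `psr_model` returns the per-epoch validation trace; on a
#' `psr_sweep`, the per-cell per-epoch results. `glance()` returns a
#' one-row (or one-row-per-cell) summary with the final accuracy and the
#' stage averages.
#'
#' @param x A `psr_model` or `psr_sweep`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy psr_model
#' @export
tidy.psr_model <- function(x, ...) x$trace

#' @rdname tidy.psr_model
#' @method tidy psr_sweep
#' @export
tidy.psr_sweep <- function(x, ...) x$results

#' @rdname tidy.psr_model
#' @method glance psr_model
#' @export
glance.psr_model <- function(x, ...) {
  st <- stage_averages(x$trace)
  out <- tibble::tibble(
    n_classes = length(x$classes),
    epochs = nrow(x$trace),
    final_accuracy = utils::tail(x$trace$val_accuracy, 1),
    best_accuracy = max(x$trace$val_accuracy)
  )
  if (nrow(st)) {
    wide <- tidyr::pivot_wider(st, names_from = "epochs",
                               values_from = "mean_accuracy",
                               names_prefix = "stage_", id_cols = c())
    out <- dplyr::bind_cols(out, wide)
  }
  out
}

#' @rdname tidy.psr_model
#' @method glance psr_sweep
#' @export
glance.psr_sweep <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(x$results, .data$tau_ms, .data$grid),
    final_accuracy = .data$val_accuracy[which.max(.data$epoch)],
    best_accuracy = max(.data$val_accuracy),
    .groups = "drop"
  )
}
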