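#' Model serialisation
#'
#' Trained objects are written to a single versioned JSON file and read
#' back bit-exactly (doubles are emitted with 17 significant digits, which
#' round-trips IEEE-754 exactly).  Three payload kinds are supported:
#' a kernel model, a folded-protein bundle (three per-state kernel models,
#' boundary profiles, optional neural refiner set) and a neural refiner
#' set alone.
#'
#' @name model-io
NULL

dt_to_list <- function(dt) lapply(dt, function(col) col)

list_to_dt <- function(lst) {
  dt <- data.table::as.data.table(lst)
  dt
}

serialize_kernel_model <- function(m) {
  list(kind = "kernel_model", condition = m$condition, ph_bin = m$ph_bin,
       n_min_mean = m$n_min_mean, n_min = m$n_min,
       primary = dt_to_list(m$primary),
       corrections = dt_to_list(m$corrections),
       n_w = as.list(m$n_w), version = m$version)
}

deserialize_kernel_model <- function(x) {
  m <- structure(list(
    condition = x$condition, ph_bin = x$ph_bin,
    n_min_mean = x$n_min_mean, n_min = x$n_min,
    primary = list_to_dt(x$primary),
    corrections = list_to_dt(x$corrections),
    n_w = unlist(x$n_w), version = x$version), class = "cs_kernel_model")
  m$primary[, n_obs := as.integer(n_obs)]
  m$corrections[, `:=`(offset = as.integer(offset),
                       n_pair = as.integer(n_pair))]
  data.table::setkey(m$primary, atom, res)
  data.table::setkey(m$corrections, atom, res, nb, offset)
  m
}

serialize_nn <- function(nn) {
  list(kind = "nn_set",
       atoms = names(nn$nets),
       nets = lapply(nn$nets, function(net) list(
         W1 = as.vector(net$W1), b1 = net$b1, W2 = net$W2, b2 = net$b2,
         dims = dim(net$W1), x_mean = net$x_mean, x_sd = net$x_sd,
         y_mean = net$y_mean, y_sd = net$y_sd)),
       config = nn$config, version = nn$version)
}

deserialize_nn <- function(x) {
  nets <- lapply(x$nets, function(net) {
    W1 <- matrix(unlist(net$W1), nrow = net$dims[[1]], ncol = net$dims[[2]])
    list(W1 = W1, b1 = unlist(net$b1), W2 = unlist(net$W2),
         b2 = unlist(net$b2), x_mean = unlist(net$x_mean),
         x_sd = unlist(net$x_sd), y_mean = net$y_mean, y_sd = net$y_sd)
  })
  names(nets) <- unlist(x$atoms)
  structure(list(nets = nets, config = x$config, version = x$version),
            class = "cs_nn_set")
}

serialize_profiles <- function(p) {
  list(kind = "boundary_profile", half_window = p$half_window,
       profile = dt_to_list(p$profile),
       state_sec = dt_to_list(p$state_sec))
}

deserialize_profiles <- function(x) {
  p <- structure(list(half_window = x$half_window,
                      profile = list_to_dt(x$profile),
                      state_sec = list_to_dt(x$state_sec)),
                 class = "cs_boundary_profile")
  p$profile[, `:=`(dist = as.integer(dist), n = as.integer(n))]
  data.table::setkey(p$profile, transition, atom, dist)
  data.table::setkey(p$state_sec, state, atom)
  p
}

#' Write a trained model to JSON
#'
#' @param model a `cs_kernel_model`, `cs_folded_model` bundle or
#'   `cs_nn_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  payload <-
    if (inherits(model, "cs_kernel_model")) serialize_kernel_model(model)
    else if (inherits(model, "cs_nn_set")) serialize_nn(model)
    else if (inherits(model, "cs_folded_model")) {
      list(kind = "folded_model",
           models = lapply(model$models, serialize_kernel_model),
           profiles = if (is.null(model$profiles)) NULL
                      else serialize_profiles(model$profiles),
           nn = if (is.null(model$nn)) NULL else serialize_nn(model$nn),
           version = model$version)
    } else stop("unsupported model class", call. = FALSE)
  json <- jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE,
                           null = "null", na = "null")
  writeLines(json, path)
  invisible(path)
}

#' Read a trained model from JSON
#'
#' @param path file written by [write_model()].
#' @return the deserialised model object.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                          simplifyVector = TRUE, simplifyDataFrame = FALSE)
  switch(x$kind,
         kernel_model = deserialize_kernel_model(x),
         nn_set = deserialize_nn(x),
         folded_model = structure(list(
           models = lapply(x$models, deserialize_kernel_model),
           profiles = if (is.null(x$profiles)) NULL
                      else deserialize_profiles(x$profiles),
           nn = if (is.null(x$nn)) NULL else deserialize_nn(x$nn),
           version = x$version), class = "cs_folded_model"),
         stop("unknown model kind: ", x$kind, call. = FALSE))
}
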