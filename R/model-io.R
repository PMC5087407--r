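# JSON serialization of fitted models. One document per model with a "type"
# discriminator; numeric values are written at full precision so that a
# write/read round trip reproduces the model exactly.

#' Write / read a fitted one-class model as JSON
#'
#' Serializes an `"ockra"`, `"parzen_oc"`, `"kmeans_oc"` or `"ocsvm_oc"` model
#' to a single JSON document with a `type` discriminator. `read_model_json`
#' restores an object that scores identically to the original.
#'
#' @param model A fitted model.
#' @param path Output/input file path.
#' @return `write_model_json` returns `path` invisibly; `read_model_json`
#'   returns the restored model.
#' @export
write_model_json <- function(model, path) {
  doc <- switch(class(model)[1],
    ockra = list(
      version = 1L, type = "ockra", n = model$n, k = model$k,
      n_members = model$n_members, master_seed = model$seed,
      feature_names = model$feature_names,
      members = lapply(model$members, function(m) {
        list(features = m$features, delta = m$delta, centroids = m$centroids)
      })
    ),
    parzen_oc = list(version = 1L, type = "parzen", n = model$n,
                     width = model$width,
                     training_points = model$training_points),
    kmeans_oc = list(version = 1L,
                     type = if (model$mode == "closest") "kmeans1" else "kmeans2",
                     n = model$n, k = model$k, width = model$width,
                     centroids = model$centroids),
    ocsvm_oc = list(version = 1L, type = "ocsvm", n = model$n,
                    gamma = model$gamma, nu = model$nu, rho = model$rho,
                    coefs = model$coefs, sv = model$sv),
    stop("cannot serialize objects of class ", class(model)[1])
  )
  json <- jsonlite::toJSON(doc, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyMatrix = TRUE)
  switch(doc$type,
    ockra = {
      members <- lapply(seq_len(nrow_or_len(doc$members)), function(i) {
        m <- member_at(doc$members, i)
        list(features = as.integer(m$features), delta = as.numeric(m$delta),
             centroids = as_matrix(m$centroids))
      })
      structure(list(members = members, k = as.integer(doc$k),
                     n_members = as.integer(doc$n_members),
                     seed = doc$master_seed, n = as.integer(doc$n),
                     feature_names = doc$feature_names),
                class = "ockra")
    },
    parzen = structure(list(training_points = as_matrix(doc$training_points),
                            width = doc$width, n = doc$n),
                       class = "parzen_oc"),
    kmeans1 = ,
    kmeans2 = structure(list(centroids = as_matrix(doc$centroids),
                             width = doc$width,
                             mode = if (doc$type == "kmeans1") "closest" else "all",
                             k = doc$k, n = doc$n),
                        class = "kmeans_oc"),
    ocsvm = structure(list(sv = as_matrix(doc$sv),
                           coefs = as.numeric(doc$coefs),
                           rho = as.numeric(doc$rho),
                           gamma = doc$gamma, nu = doc$nu, n = doc$n),
                      class = "ocsvm_oc"),
    stop("unknown model type: ", doc$type)
  )
}

# jsonlite may return a member list either as a data.frame (homogeneous) or
# as a plain list; these helpers paper over the two shapes.
nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
member_at <- function(x, i) {
  if (is.data.frame(x)) {
    list(features = x$features[[i]], delta = x$delta[[i]],
         centroids = x$centroids[[i]])
  } else {
    x[[i]]
  }
}
as_matrix <- function(x) {
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  m
}
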