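#' Construct an encoder object
#'
#' An encoder maps a single word token to a fixed-length numeric vector,
#' deterministically (same token, same vector). The package ships a seeded
#' [mock_encoder()] for synthetic experiments and a [tsv_encoder()] that
#' serves cached embeddings (e.g., exported from a pretrained uncased
#' transformer) for offline reproducibility.
#'
#' @param name Encoder identifier.
#' @param dim Output dimensionality (constant across calls).
#' @param encode_fn Function(token) -> numeric vector of length `dim`.
#' @return A `qcla_encoder` object with an internal token cache.
#' @export
new_encoder <- function(name, dim, encode_fn) {
  stopifnot(is.function(encode_fn), dim >= 1)
  structure(
    list(name = name, dim = as.integer(dim), encode_fn = encode_fn,
         cache = new.env(parent = emptyenv())),
    class = "qcla_encoder"
  )
}

#' @export
print.qcla_encoder <- function(x, ...) {
  cat(sprintf("<qcla_encoder '%s', dim = %d>\n", x$name, x$dim))
  invisible(x)
}

# Stable 31-bit string hash (independent of R session state).
token_hash <- function(token) {
  h <- 0
  for (b in utf8ToInt(token)) h <- (h * 131 + b) %% 2147483629
  as.integer(h)
}

unit <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("cannot normalize a zero vector")
  v / nv
}

#' Seeded mock word encoder
#'
#' Maps every token to a deterministic pseudo-random unit "noise" vector
#' (seeded from a hash of the token). Tokens belonging to a synthetic
#' lexicon additionally receive a class-direction component: the mean of
#' the orthonormal direction vectors of the emotions owning the token,
#' scaled by `class_weight`. Responses from different emotions are thereby
#' linearly separable by construction when word noise is absent and
#' lexicons are disjoint.
#'
#' @param lexicons Optional named list of emotion lexicons (see
#'   [build_lexicons()]). Without lexicons every token is pure noise.
#' @param dim Embedding dimensionality, default 768.
#' @param seed Integer seed for class directions and token noise.
#' @param class_weight Scale of the class-direction component.
#' @param noise_weight Scale of the token-specific unit noise vector.
#' @return A `qcla_encoder`.
#' @export
#' @examples
#' enc <- mock_encoder(dim = 16, seed = 1)
#' identical(encode_word(enc, "sad"), encode_word(enc, "sad"))
mock_encoder <- function(lexicons = NULL, dim = 768L, seed = 1L,
                         class_weight = 1, noise_weight = 0.4) {
  dim <- as.integer(dim)
  dirs <- NULL
  if (!is.null(lexicons)) {
    stopifnot(dim >= length(lexicons))
    dirs <- withr::with_seed(child_seed(seed, 7L), {
      qr.Q(qr(matrix(rnorm(dim * length(lexicons)), dim)))
    })
    colnames(dirs) <- names(lexicons)
  }
  encode_fn <- function(token) {
    noise <- withr::with_seed(child_seed(seed, token_hash(token)), {
      unit(rnorm(dim))
    })
    if (is.null(dirs)) return(noise_weight * noise)
    owners <- names(lexicons)[vapply(lexicons, function(l) token %in% l,
                                     logical(1))]
    if (!length(owners)) return(noise_weight * noise)
    class_weight * rowMeans(dirs[, owners, drop = FALSE]) +
      noise_weight * noise
  }
  new_encoder(sprintf("mock-%d", dim), dim, encode_fn)
}

#' Encoder backed by a token-embedding cache file
#'
#' Reads a TSV with a `token` column followed by the embedding columns
#' (one row per token) and serves lookups from it. This is the offline
#' adapter for embeddings exported from a pretrained model.
#'
#' @param path Path to the tab-delimited cache (header row required).
#' @param name Encoder identifier; defaults to the file name.
#' @return A `qcla_encoder`. Unknown tokens raise an error.
#' @export
tsv_encoder <- function(path, name = basename(path)) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(names(tab)[1] == "token")
  mat <- as.matrix(tab[, -1, drop = FALSE])
  rownames(mat) <- tab$token
  encode_fn <- function(token) {
    if (!token %in% rownames(mat)) {
      stop(sprintf("token '%s' not present in embedding cache", token))
    }
    as.numeric(mat[token, ])
  }
  new_encoder(name, ncol(mat), encode_fn)
}

#' Write a token-embedding cache for an encoder
#'
#' @param encoder A `qcla_encoder`.
#' @param tokens Character vector of tokens to materialize.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_embedding_cache <- function(encoder, tokens, path) {
  tokens <- unique(tokens)
  mat <- t(vapply(tokens, function(tk) encode_word(encoder, tk),
                  numeric(encoder$dim)))
  out <- data.frame(token = tokens, mat, check.names = FALSE)
  names(out) <- c("token", sprintf("d%03d", seq_len(encoder$dim)))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Encode a single word
#'
#' @param encoder A `qcla_encoder`.
#' @param token A cleaned, non-empty single word.
#' @return Numeric vector of length `encoder$dim`. Repeat calls are
#'   bit-identical (results are cached).
#' @export
encode_word <- function(encoder, token) {
  stopifnot(inherits(encoder, "qcla_encoder"))
  if (!is.character(token) || length(token) != 1L || !nzchar(token)) {
    stop("token must be a single non-empty word")
  }
  if (!is.null(encoder$cache[[token]])) return(encoder$cache[[token]])
  v <- encoder$encode_fn(token)
  if (length(v) != encoder$dim || any(!is.finite(v))) {
    stop("encoder returned a malformed vector")
  }
  encoder$cache[[token]] <- v
  v
}

#' Encode a descriptive-word response
#'
#' A response of one to five words is represented as the unweighted
#' arithmetic mean of the per-word embeddings.
#'
#' @param encoder A `qcla_encoder`.
#' @param words Character vector of 1-5 cleaned words.
#' @return Numeric vector of length `encoder$dim`.
#' @export
encode_response <- function(encoder, words) {
  if (length(words) < 1L) stop("a response needs at least one word")
  vs <- vapply(words, function(w) encode_word(encoder, w),
               numeric(encoder$dim))
  if (length(words) == 1L) as.numeric(vs) else rowMeans(vs)
}

#' Build the design matrix for one feature set
#'
#' @param records Cleaned record tibble.
#' @param feature_set One of `"words"` (response embeddings, 768 columns for
#'   the default encoder), `"scales"` (the four totals), `"combined"`
#'   (embedding columns followed by the four totals), or `"items"` (all 26
#'   individual scale items).
#' @param encoder Required for `"words"` and `"combined"`.
#' @return A `qcla_features` object: list with `X` (numeric matrix, one row
#'   per record, in record order), `narrative_id`, `label` (factor with the
#'   canonical emotion levels), and `feature_set`.
#' @export
build_feature_matrix <- function(records,
                                 feature_set = c("words", "scales",
                                                 "combined", "items"),
                                 encoder = NULL) {
  feature_set <- match.arg(feature_set)
  totals <- as.matrix(records[paste0(names(SCALES), "_total")])
  colnames(totals) <- names(SCALES)
  X <- switch(
    feature_set,
    scales = totals,
    items = {
      cols <- unlist(lapply(names(SCALES), function(s) {
        sprintf("%s_%d", s, seq_len(SCALES[[s]]$items))
      }))
      as.matrix(records[cols])
    },
    words = ,
    combined = {
      if (is.null(encoder)) stop("feature_set '", feature_set,
                                 "' needs an encoder")
      wl <- record_words(records)
      emb <- t(vapply(wl, function(w) encode_response(encoder, w),
                      numeric(encoder$dim)))
      colnames(emb) <- sprintf("e%03d", seq_len(ncol(emb)))
      if (feature_set == "combined") cbind(emb, totals) else emb
    }
  )
  storage.mode(X) <- "double"
  rownames(X) <- records$record_id
  structure(
    list(X = X,
         narrative_id = records$narrative_id,
         label = factor(records$true_emotion, levels = EMOTIONS),
         feature_set = feature_set),
    class = "qcla_features"
  )
}

#' @export
print.qcla_features <- function(x, ...) {
  cat(sprintf("<qcla_features '%s': %d records x %d features, %d narratives>\n",
              x$feature_set, nrow(x$X), ncol(x$X),
              length(unique(x$narrative_id))))
  invisible(x)
}
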