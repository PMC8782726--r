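# The 1D channel: an unsupervised embedding of substructure tokens trained
# with skip-gram + negative sampling over substructure sentences. A molecule
# vector is the sum of its token vectors, so vectors are additive over
# sentence concatenation by construction.

#' Embedding hyperparameters
#'
#' @param dim embedding dimension (default 100).
#' @param window skip-gram context width (default 10; sentences interleave
#'   radii per atom, so a window of 10 spans roughly 5 neighbouring atoms at
#'   radius 1).
#' @param min_count minimum token frequency for vocabulary inclusion.
#' @param epochs training epochs.
#' @param negative negative samples per positive pair.
#' @param alpha initial learning rate.
#' @param seed RNG seed for initialisation and sampling; fixed seed plus the
#'   single-threaded trainer gives bit-reproducible vectors.
#' @param radius sentence environment radius used with this model.
#' @return an `embedding_hp` list.
#' @export
embedding_hp <- function(dim = 100L, window = 10L, min_count = 1L,
                         epochs = 5L, negative = 5L, alpha = 0.025,
                         seed = 1L, radius = 1L) {
  if (dim < 2) .fatal_config("embedding dim must be >= 2")
  if (epochs < 1) .fatal_config("epochs must be >= 1")
  if (window < 1) .fatal_config("window must be >= 1")
  structure(list(dim = as.integer(dim), window = as.integer(window),
                 min_count = as.integer(min_count), epochs = as.integer(epochs),
                 negative = as.integer(negative), alpha = alpha,
                 seed = as.integer(seed), radius = as.integer(radius)),
            class = "embedding_hp")
}

#' Train the substructure-token embedding model
#'
#' Skip-gram with negative sampling over substructure sentences. Tokens with
#' corpus frequency below `min_count` are excluded from the vocabulary.
#' Training is sequential (single worker), so a fixed seed reproduces the
#' vector matrix bit-for-bit.
#'
#' @param sentences list of substructure sentences ([mol_sentences()]).
#' @param hp hyperparameters from [embedding_hp()].
#' @param unk_policy handling of out-of-vocabulary tokens at embedding time:
#'   `"skip"` (default) or `"zero_vector"`; numerically identical, kept for
#'   ablation bookkeeping.
#' @return an `embedding_model`: list with `vocab` (named index), `freq`,
#'   `vectors` (|vocab| x dim matrix, rownames = tokens), `hp`, `unk_policy`.
#' @export
train_embedding <- function(sentences, hp = embedding_hp(),
                            unk_policy = c("skip", "zero_vector")) {
  unk_policy <- match.arg(unk_policy)
  sentences <- Filter(function(s) !is.null(s) && length(s) > 0, sentences)
  if (length(sentences) == 0L) .fatal_input("empty sentence corpus")

  freq <- table(unlist(sentences, use.names = FALSE))
  keep <- freq[freq >= hp$min_count]
  if (length(keep) == 0L)
    .fatal_empty(paste0("empty vocabulary: no token occurs at least min_count = ",
                        hp$min_count, " times"))
  vocab <- stats::setNames(seq_along(keep), names(keep))

  coded <- lapply(sentences, function(s) {
    ids <- unname(vocab[s])
    ids[!is.na(ids)]
  })
  coded <- Filter(length, coded)

  vectors <- .sgns_train(coded, length(vocab), as.numeric(keep),
                         hp$dim, hp$window, hp$negative, hp$epochs,
                         hp$alpha, as.double(hp$seed))
  rownames(vectors) <- names(vocab)

  structure(list(vocab = vocab, freq = as.integer(keep), vectors = vectors,
                 hp = hp, unk_policy = unk_policy),
            class = "embedding_model")
}

#' @export
print.embedding_model <- function(x, ...) {
  cat("<embedding_model> ", length(x$vocab), " tokens x ", x$hp$dim,
      " dims (window ", x$hp$window, ", epochs ", x$hp$epochs,
      ", seed ", x$hp$seed, ")\n", sep = "")
  invisible(x)
}

#' Embed a molecule by summing its substructure vectors
#'
#' The molecule vector is the component-wise sum of the vectors of its
#' sentence tokens. Out-of-vocabulary tokens contribute nothing under the
#' default `skip` policy (a zero vector under `zero_vector` — numerically
#' identical, kept for ablation bookkeeping of OOV counts). A sentence with
#' no in-vocabulary token yields the zero vector with a warning.
#'
#' @param model an `embedding_model`.
#' @param sentence character vector of tokens from [mol_sentence()].
#' @return numeric vector of length `model$hp$dim`.
#' @export
embed_molecule <- function(model, sentence) {
  stopifnot(inherits(model, "embedding_model"))
  idx <- model$vocab[sentence]
  idx <- unname(idx[!is.na(idx)])
  if (length(idx) == 0L) {
    warning("sentence has no in-vocabulary token; returning the zero vector")
    return(numeric(model$hp$dim))
  }
  colSums(model$vectors[idx, , drop = FALSE])
}

#' Save an embedding model to a directory
#'
#' Layout: `vocab.tsv` (token, index, frequency), `vectors.bin` (doubles,
#' row-major over tokens), `hyperparameters.json`, and a plain-text
#' `model-card.txt` recording engine versions and the seed. The round trip
#' through [load_embedding()] reproduces the vectors bit-for-bit.
#'
#' @param model an `embedding_model`.
#' @param dir output directory (created if needed).
#' @export
save_embedding <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(
    data.frame(token = names(model$vocab), index = unname(model$vocab),
               frequency = model$freq),
    file.path(dir, "vocab.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  con <- file(file.path(dir, "vectors.bin"), "wb")
  writeBin(as.vector(t(model$vectors)), con, size = 8, endian = "little")
  close(con)
  jsonlite::write_json(
    c(model$hp[names(model$hp) != "alpha"],
      list(alpha = model$hp$alpha, unk_policy = model$unk_policy)),
    file.path(dir, "hyperparameters.json"), auto_unbox = TRUE, digits = NA)
  writeLines(c(
    "substructure-token embedding model",
    paste0("trained: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    paste0("seed: ", model$hp$seed),
    paste0("engines: ", paste(names(engine_versions()),
                              unlist(engine_versions()), sep = "=",
                              collapse = ", "))
  ), file.path(dir, "model-card.txt"))
  invisible(dir)
}

#' Load an embedding model saved by [save_embedding()]
#' @param dir model directory.
#' @return an `embedding_model`.
#' @export
load_embedding <- function(dir) {
  vt <- file.path(dir, "vocab.tsv")
  vb <- file.path(dir, "vectors.bin")
  hj <- file.path(dir, "hyperparameters.json")
  if (!all(file.exists(c(vt, vb, hj))))
    .fatal_input(paste0("not an embedding model directory: ", dir))
  vocab_tab <- utils::read.delim(vt, stringsAsFactors = FALSE,
                                 colClasses = c("character", "integer", "integer"))
  hp_raw <- jsonlite::read_json(hj, simplifyVector = TRUE)
  hp <- embedding_hp(dim = hp_raw$dim, window = hp_raw$window,
                     min_count = hp_raw$min_count, epochs = hp_raw$epochs,
                     negative = hp_raw$negative, alpha = hp_raw$alpha,
                     seed = hp_raw$seed, radius = hp_raw$radius)
  con <- file(vb, "rb")
  raw <- readBin(con, "double", n = nrow(vocab_tab) * hp$dim, size = 8,
                 endian = "little")
  close(con)
  vectors <- matrix(raw, nrow = nrow(vocab_tab), ncol = hp$dim, byrow = TRUE)
  rownames(vectors) <- vocab_tab$token
  structure(list(vocab = stats::setNames(vocab_tab$index, vocab_tab$token),
                 freq = vocab_tab$frequency, vectors = vectors, hp = hp,
                 unk_policy = if (is.null(hp_raw$unk_policy)) "skip"
                              else hp_raw$unk_policy),
            class = "embedding_model")
}
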