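# Human-editable YAML experiment configuration: corpus spec, encoder,
# aggregation strategy and training settings in one file. Used by the
# command-line interface (inst/cli/mlner) and handy for scripted runs.

#' Read an experiment configuration file
#'
#' The YAML file may contain four sections, all optional: `corpus` (either
#' the full [corpus_spec()] fields, or just `n_sentences` / `seed` to use
#' [default_corpus_spec()]), `encoder` ([encoder_config()] fields),
#' `aggregate` (`method`, `layer_subset`, `n_fusion_heads`) and `train`
#' ([train_config()] fields). Missing sections fall back to the desk-scale
#' defaults.
#'
#' @param path YAML file path.
#' @return List with elements `corpus_spec`, `encoder`, `aggregator`,
#'   `train`.
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  corpus <- raw$corpus
  corpus_spec <- if (is.null(corpus)) {
    default_corpus_spec()
  } else if (!is.null(corpus$entity_lexicons)) {
    corpus_spec(
      entity_lexicons = lapply(corpus$entity_lexicons, as.character),
      context_alphabet = as.character(corpus$context_alphabet),
      templates = as.character(corpus$templates),
      n_sentences = corpus$n_sentences %||% 1000L,
      max_entities_per_sentence = corpus$max_entities_per_sentence %||% 3L,
      seed = corpus$seed %||% 1L)
  } else {
    default_corpus_spec(n_sentences = corpus$n_sentences %||% 1000L,
                        seed = corpus$seed %||% 1L)
  }
  encoder <- do.call(encoder_config_desk, raw$encoder %||% list())
  aggregator <- do.call(aggregator_config,
                        utils::modifyList(list(n_fusion_heads = 4L),
                                          raw$aggregate %||% list()))
  train <- do.call(train_config_desk, raw$train %||% list())
  list(corpus_spec = corpus_spec, encoder = encoder, aggregator = aggregator,
       train = train)
}

#' Write an experiment configuration file
#'
#' Serializes the four sections back to YAML; a file written here reads back
#' to an equivalent configuration via [read_experiment_config()].
#'
#' @param config List as returned by [read_experiment_config()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_experiment_config <- function(config, path) {
  spec <- config$corpus_spec
  enc <- config$encoder
  out <- list(
    corpus = list(entity_lexicons = spec$entity_lexicons,
                  context_alphabet = spec$context_alphabet,
                  templates = spec$templates,
                  n_sentences = spec$n_sentences,
                  max_entities_per_sentence = spec$max_entities_per_sentence,
                  seed = spec$seed),
    encoder = enc[c("n_layers", "hidden_size", "n_encoder_heads",
                    "max_sentence_length", "dropout_rate", "ffn_mult",
                    "activation", "seed")],
    aggregate = unclass(config$aggregator),
    train = config$train[c("epochs", "batch_size", "learning_rate",
                           "weight_decay", "seed")]
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
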