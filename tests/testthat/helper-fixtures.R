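# Shared small fixtures built in code.

hep_config <- function() {
  segmenter_config(
    lexicon = c("JIA XING", "BING DU XING GAN YAN", "GAN HUN MI",
                "JI XING", "ZHONG XING", "YA JI XING", "JIA GAN",
                "BU BAN", "BAN"),
    stop_words = "BAN",
    negation_words = "BU BAN"
  )
}

# random token sequences over a small alphabet, for property tests
random_tokens <- function(len, alphabet = letters[1:5]) {
  if (len == 0) character(0) else sample(alphabet, len, replace = TRUE)
}

# random ontology over a small alphabet: a few random groups
random_ontology <- function(alphabet = letters[1:5], fallback = FALSE) {
  n_groups <- sample(0:3, 1)
  if (n_groups == 0) return(term_ontology(fallback = fallback))
  groups <- lapply(seq_len(n_groups), function(i) {
    synonym_group(paste0("g", i),
                  sample(alphabet, min(length(alphabet), sample(2:3, 1))),
                  stats::runif(1, 0.05, 1))
  })
  term_ontology(dplyr::bind_rows(groups), fallback = fallback)
}
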