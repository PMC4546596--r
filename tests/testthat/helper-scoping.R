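# Hand-derived temporal scoping fixture: 12 documents covering the three
# scoping rules (single time, multiple times in one statement, carry-forward
# across statements).  `want` maps each event surface to its expected time
# surface (NA = unspecified).

scoping_lex <- function() {
  add_term(lexicon_set(), c("咳嗽", "发热", "腹痛", "头痛"), "symptom",
           "core")
}

scoping_cases <- list(
  list(doc = "3天前咳嗽。",
       want = c(咳嗽 = "3天前")),                         # single time
  list(doc = "咳嗽。",
       want = c(咳嗽 = NA)),                              # no time anywhere
  list(doc = "3天前咳嗽。发热。",
       want = c(咳嗽 = "3天前", 发热 = "3天前")),         # carry forward
  list(doc = "3天前咳嗽，昨天发热。",
       want = c(咳嗽 = "3天前", 发热 = "昨天")),          # two times split
  list(doc = "3天前咳嗽。昨天发热。",
       want = c(咳嗽 = "3天前", 发热 = "昨天")),          # one each
  list(doc = "咳嗽。3天前发热。",
       want = c(咳嗽 = NA, 发热 = "3天前")),              # late first time
  list(doc = "3天前咳嗽，发热。",
       want = c(咳嗽 = "3天前", 发热 = "3天前")),         # covers clause 2
  list(doc = "3天前咳嗽。昨天发热。腹痛。",
       want = c(咳嗽 = "3天前", 发热 = "昨天", 腹痛 = "昨天")),
  list(doc = "咳嗽3天前。",
       want = c(咳嗽 = "3天前")),                         # time after event
  list(doc = "3天前咳嗽，昨天发热，今晨腹痛。",
       want = c(咳嗽 = "3天前", 发热 = "昨天", 腹痛 = "今晨")),
  list(doc = "发热，今晨腹痛。",
       want = c(发热 = "今晨", 腹痛 = "今晨")),           # rule 1, mid time
  list(doc = "昨天咳嗽。发热，3天前腹痛，今晨头痛。",
       want = c(咳嗽 = "昨天", 发热 = "昨天",             # prefix inherits
                腹痛 = "3天前", 头痛 = "今晨")))          # carried time

# Build the assign_time_scopes() input for a document: per statement, the
# extracted temporal terms and tagged events, shifted to document offsets.
build_scope_input <- function(doc, lex) {
  sts <- split_statements(doc)
  lapply(seq_len(nrow(sts)), function(si) {
    st <- sts$text[si]
    shift <- function(tab) {
      tab$start <- tab$start + sts$start[si]
      tab$end <- tab$end + sts$start[si]
      tab
    }
    list(times = shift(extract_temporal_terms(st)),
         events = shift(tag_terms(st, lex)))
  })
}

# Count correct event-time assignments for one fixture case.
scoping_correct <- function(case, lex) {
  got <- assign_time_scopes(build_scope_input(case$doc, lex))
  if (nrow(got) != length(case$want)) return(c(0L, length(case$want)))
  ok <- vapply(seq_len(nrow(got)), function(k) {
    want_t <- unname(case$want[[got$surface[k]]])
    if (is.na(want_t)) is.na(got$time_surface[k])
    else !is.na(got$time_surface[k]) && got$time_surface[k] == want_t
  }, logical(1))
  c(sum(ok), length(ok))
}
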