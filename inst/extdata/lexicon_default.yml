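# Default 15-topic nicotine lexicon.
#
# This pattern set is a RECONSTRUCTION from published descriptions of the
# topics; it is not a verbatim copy of any study's unpublished pattern
# lists. Edit freely: each pattern is a single `kind: phrase` entry where
# kind is one of unigram, bigram, ordered_group. Phrases are written in
# surface form; the reader normalizes them (lower-casing, stop-word
# removal, lemmatization) so they match normalized tweet tokens exactly.
topics:
  person tagging:
    - unigram: "@person"
  addiction:
    - unigram: addicted
    - unigram: addiction
    - unigram: craving
    - bigram: nicotine addiction
  appeal:
    - ordered_group: love nicotine
    - ordered_group: like nicotine
    - bigram: nicotine buzz
  NRT:
    - unigram: patch
    - unigram: gum
    - unigram: nrt
    - bigram: nicotine replacement
  vaping:
    - unigram: vape
    - unigram: vaping
    - unigram: juul
    - unigram: ecig
    - unigram: ecigarette
  smoking:
    - unigram: smoking
    - unigram: cigarette
    - unigram: cigar
    - unigram: tobacco
  nicotine health risks:
    - ordered_group: nicotine brain
    - ordered_group: nicotine lungs
    - bigram: health risk
    - unigram: respiratory
    - ordered_group: nicotine effects
  withdrawal:
    - unigram: withdrawal
    - bigram: nicotine withdrawal
  quit nicotine:
    - bigram: cold turkey
    - bigram: nicotine free
    - ordered_group: quit nicotine
  cessation:
    - ordered_group: quit smoking
    - ordered_group: stop smoking
    - unigram: cessation
  polysubstance use:
    - unigram: alcohol
    - unigram: beer
    - unigram: vodka
    - unigram: wine
    - unigram: whiskey
    - unigram: booze
  caffeine:
    - unigram: coffee
    - unigram: caffeine
    - unigram: espresso
  underage use:
    - unigram: teen
    - unigram: underage
    - bigram: high school
    - ordered_group: kids nicotine
  new products:
    - bigram: nicotine shot
    - ordered_group: boost nicotine
    - ordered_group: supplement nicotine
    - bigram: new product
  nicotine is safe:
    - ordered_group: nicotine is safe
    - ordered_group: nicotine not harmful
    - unigram: harmless
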