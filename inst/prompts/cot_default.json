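{
  "version": "1",
  "template": "{instruction}\n\nSentence: {demo_text}\nLabel: {demo_label}\nExplanation: {demo_explanation}\n\nSentence: {query_text}\nLabel: {query_label}\nExplanation:",
  "instructions": {
    "ner": "Mark every entity in the sentence with its type and explain step by step why the marked mentions are entities. End with 'So the label is <label>.'",
    "re": "Decide the relation between the entity pair in the sentence and explain step by step how the wording supports it. End with 'So the label is <label>.'",
    "nli": "Decide whether the hypothesis is entailed by, contradicts, or is neutral to the premise, and explain step by step. End with 'So the label is <label>.'"
  }
}
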