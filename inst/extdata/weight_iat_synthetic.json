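{
  "attribute_names": ["good", "bad"],
  "concept_names": ["overweight people", "thin people"],
  "attribute_items": [
    ["joy", "love", "peace", "wonderful", "pleasure", "glorious", "laughter", "happy"],
    ["agony", "terrible", "horrible", "nasty", "evil", "awful", "failure", "hurt"]
  ],
  "concept_items": [
    ["overweight_silhouette_1.png", "overweight_silhouette_2.png", "overweight_silhouette_3.png",
     "overweight_silhouette_4.png", "overweight_silhouette_5.png", "overweight_silhouette_6.png"],
    ["thin_silhouette_1.png", "thin_silhouette_2.png", "thin_silhouette_3.png",
     "thin_silhouette_4.png", "thin_silhouette_5.png", "thin_silhouette_6.png"]
  ],
  "_comment": "Synthetic weight-attitude stimulus set for examples and simulation; the image identifiers are placeholders, never decoded by the headless engine."
}
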