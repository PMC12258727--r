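category	pattern
protein aggregation & membrane stability	dehydrin|late embryogenesis|\bLEA\b|ABA-inducible|annexin|membrane stabili[sz]|phospholipid-binding|PEBP|phosphatidylethanolamine-binding
protein folding & chaperone activity	heat shock|\bHSP\b|chaperon|protein folding|peptidyl-prolyl|disulfide isomerase|\bcpn\b|ClpB
metabolism & osmoregulation	malate synthase|sucrose synthase|trehalose|raffinose|galactinol|proline|betaine|invertase|glycolysis|osmoregulat|osmotic|starch|fructan|aldose reductase
detoxification & ROS scavenging	aldo-keto reductase|glutathione|peroxidase|catalase|superoxide dismutase|ascorbate|thioredoxin|peroxiredoxin|glyoxalase|oxidative stress|detoxif
lipid metabolism	lipid transfer|lipoxygenase|fatty acid|desaturase|phospholipase|oleosin|caleosin|lipase
antifreeze & cell wall modification	antifreeze|chitinase|thaumatin|zeamatin|ice.binding|xyloglucan|pectin|expansin|cell wall
cold signal transduction	calmodulin|EF-hand|calcium-binding|\bCBF\b|\bDREB\b|\bICE1\b|kinase|14-3-3|signal transduction|phosphatase 2C
cytoskeletal organization	actin|tubulin|myosin|kinesin|microtubule|cytoskelet|profilin|villin|actin-depolymerizing
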