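# Anatomical merge map: 13 GTEx brain region labels onto overarching
# groups.  The six main groups follow brain anatomy (the basal ganglia
# comprise the caudate, nucleus accumbens and putamen; cerebellum and
# cerebellar hemisphere samples come from the same site; the cortical
# regions are grouped).  Amygdala and hippocampus stay as singleton
# groups and are typically flagged as too small to form a mini-network.
basal ganglia:
  - Brain caudate (basal ganglia)
  - Brain nucleus accumbens (basal ganglia)
  - Brain putamen (basal ganglia)
cerebellum:
  - Brain cerebellum
  - Brain cerebellar hemisphere
cortex:
  - Brain cortex
  - Brain frontal cortex BA9
  - Brain anterior cingulate cortex BA24
hypothalamus:
  - Brain hypothalamus
spinal cord:
  - Brain spinal cord cervical c1
substantia nigra:
  - Brain substantia nigra
amygdala:
  - Brain amygdala
hippocampus:
  - Brain hippocampus
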