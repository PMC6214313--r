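name,value
nodes,6995
edges,17464
components,18
cut_nodes,569
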