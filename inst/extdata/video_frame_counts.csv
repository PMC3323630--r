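category,group,n_frames
total_classified,total,3122
sand,substrate,442
rhodolith,substrate,992
high_reef,substrate,55
medium_reef,substrate,147
low_reef,substrate,478
flat_reef,substrate,620
obscured_reef,substrate,412
ecklonia,biota,536
other_macroalgae,biota,906
sessile_invertebrates,biota,636
hard_coral,biota,1
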