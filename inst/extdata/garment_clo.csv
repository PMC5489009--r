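code,description,clo
briefs,Underwear briefs,0.04
bra,Bra,0.01
t_shirt,T-shirt,0.08
shirt_short,Short-sleeve dress shirt,0.19
shirt_long,Long-sleeve dress shirt,0.25
blouse,Long-sleeve blouse,0.25
sweater,Long-sleeve sweater,0.28
jacket,Single-breasted jacket,0.36
trousers,Straight trousers,0.25
skirt,Knee-length skirt,0.23
dress,Long-sleeve dress,0.40
shorts,Walking shorts,0.08
socks,Calf-length socks,0.03
tights,Pantyhose,0.02
shoes,Shoes,0.02
boots,Boots,0.10
coat,Overcoat,0.60
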