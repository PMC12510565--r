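# Adjacency of the 16 Chengdu-Chongqing agglomeration cities, derived
# from shared administrative borders. Editable: symmetry is enforced on
# load, so listing a neighbour on either side is sufficient.
Chengdu: [Deyang, Ziyang, Meishan, Yaan]
Deyang: [Chengdu, Mianyang, Suining, Ziyang]
Mianyang: [Deyang, Suining, Nanchong]
Suining: [Deyang, Mianyang, Nanchong, Chongqing, Ziyang]
Nanchong: [Mianyang, Suining, Guangan, Dazhou, Chongqing]
Guangan: [Nanchong, Dazhou, Chongqing]
Dazhou: [Nanchong, Guangan, Chongqing]
Chongqing: [Suining, Nanchong, Guangan, Dazhou, Luzhou, Neijiang, Ziyang]
Ziyang: [Chengdu, Deyang, Suining, Neijiang, Meishan, Chongqing]
Neijiang: [Ziyang, Zigong, Luzhou, Chongqing]
Zigong: [Neijiang, Yibin, Luzhou, Leshan]
Luzhou: [Chongqing, Neijiang, Zigong, Yibin]
Yibin: [Luzhou, Zigong, Leshan]
Leshan: [Yibin, Zigong, Meishan, Yaan]
Meishan: [Chengdu, Ziyang, Leshan, Yaan]
Yaan: [Chengdu, Meishan, Leshan]
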