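tree,detect,actual,predicted,rate_printed
1,47,65,70,7.6
2,43,73,63,13.6
3,37,58,55,5.1
4,42,56,61,8
5,68,107,100,6.5
6,64,93,94,1.0
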