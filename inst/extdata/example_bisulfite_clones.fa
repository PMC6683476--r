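>clone01_synthetic
CATAATGATATCACTCCGTCAAGACAGTGGCTTAGAAGTTTATTTTGTTGATTTAGAGTG
>clone02_synthetic
CATAATGATATCACTCCGTCAAGACAGTGGCTTAGAAGTTTATTTTGTTGATTTAGAGTG
>clone03_synthetic
CATAATGATATCACTCCGTCAAGACAGTGGCTTAGAAGTTTATTTTGTTGATTTAGAGTG
>clone04_synthetic
CATAATGATATCACTCCGTCAAGACAGTGGCTTAGAAGTTTATTTTGTTGATTTAGAGTG
>clone05_synthetic
CATAATGATATCACTCCGTCAAGACAGTGGCTTAGAAGTTTATTTTGTTGATTTAGAGTG
>clone06_synthetic
CATAATGATATCACTCCGTCAAGACAGTGGCTTAGAAGTTTATTTTGTTGATTTAGAGTG
>clone07_synthetic
CATAATGATATCACTCCGTCAAGACAGTGGCTTAGAAGTTTATTTTGTTGATTTAGAGTG
>clone08_synthetic
CATAATGATATCACTCCGTCAAGACAGTGGCTTAGAAGTTTATTTTGTTGATTTAGAGTG
>clone09_synthetic
CATAATGATATCACTCCGTCAAGACAGTGGCTTAGAAGTTTATTTTGTTGATTTAGAGTG
>clone10_synthetic
CATAATGATATCACTCCGTCAAGACAGTGGCTTAGAAGTTTATTTTGTTGATTTAGAGTG
>clone11_synthetic
CATAATGATATCACTCCGTCAAGACAGTGGCTTAGAAGTTTATTTTGTTGATTTAGAGTG
>clone12_synthetic
CATAATGATATCACTCCGTCAAGACAGTGGCTTAGAAGTTTATTTTGTTGATTTAGAGTG
>clone13_synthetic
CATAATGATATCACTCCGTCAAGACAGTGGCTTAGAAGTTTATTTTGTTGATTTAGAGTG
>clone14_synthetic
CATAATGATATCACTCCGTCAAGACAGTGGCTTAGAAGTTTATTTTGTTGATTTAGAGTG
>clone15_synthetic
CATAATGATATCACTCCGTCAAGACAGTGGCTTAGAAGTTTATTTTGTTGATTTAGAGTG
>clone16_synthetic
CATAATGATATCACTCCGTCAAGACAGTGGCTTAGAAGTTTATTTTGTTGATTTAGAGTG
>clone17_synthetic
CATAATGATATCACTCCGTCAAGACAGTGGCTTAGAAGTTTATTTTGTTGATTTAGAGTG
>clone18_synthetic
CATAATGATATCACTCCGTCAAGACAGTGGCTTAGAAGTTTATTTTGTTGATTTAGAGTG
>clone19_synthetic
CATAATGATATCACTCCGTCAAGACAGTGGCTTAGAAGTTTATCTTGTTGATTTAGAGTG
>clone20_synthetic
CATAATGATATCACTCCGTCAAGACAGTGGCTTAGAAGTTTATTTTGTTGATTTAGAGTG
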