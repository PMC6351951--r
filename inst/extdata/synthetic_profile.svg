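<svg xmlns="http://www.w3.org/2000/svg" viewBox="-10 -10 181 370">
  <path d="M 0,0 Q 38.9984219,96.9171648 16.9798204,97.2891119 Q 160.856961,417.579881 0,349.401015" fill="none" stroke="black"/>
</svg>
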